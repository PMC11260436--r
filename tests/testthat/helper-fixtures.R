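# Shared fixtures, all built in code at test time.

# Cosine-phase sinusoidal angle trace: peaks land exactly on the sample grid
# when freq divides fps.
make_sinusoid <- function(freq = 3, half_amp = 18, baseline = 23, fps = 30,
                          duration = 10) {
  t <- seq(0, duration, by = 1 / fps)
  displacement_signal(baseline + half_amp * cos(2 * pi * freq * t), fps)
}

# Least-squares sinusoid amplitude: an estimator of filter gain independent
# of peak detection and immune to sampling-phase bias.
fit_sine_amplitude <- function(values, freq, fps) {
  t <- (seq_along(values) - 1) / fps
  X <- cbind(1, sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  b <- qr.solve(X, values)
  sqrt(b[2]^2 + b[3]^2)
}

# Hand-built segmentation over a synthetic event vector: tap k has valley
# value valleys[k], peak value peaks[k]; events spaced evenly.
make_manual_segmentation <- function(peaks, valleys, fps = 10, spacing = 5L) {
  n <- length(peaks)
  stopifnot(length(valleys) == n + 1L)
  v_idx <- 1L + (0:n) * 2L * spacing
  p_idx <- v_idx[seq_len(n)] + spacing
  values <- numeric(max(v_idx))
  values[v_idx] <- valleys
  values[p_idx] <- peaks
  sig <- displacement_signal(values, fps)
  seg <- structure(list(valley_indices = v_idx, peak_indices = p_idx,
                        taps = data.frame(valley = v_idx[seq_len(n)],
                                          peak = p_idx,
                                          next_valley = v_idx[-1])),
                   class = "cycle_segmentation")
  list(signal = sig, seg = seg)
}

# Small separable labeled table for model tests: informative features carry
# the class signal, noise features do not.
make_toy_model_table <- function(n_per_class = 30, n_noise = 5, sep = 3,
                                 seed = 1) {
  set.seed(seed)
  scores <- rep(0:3, each = n_per_class)
  n <- length(scores)
  tab <- data.frame(matrix(rnorm(n * 13), nrow = n))
  names(tab) <- tapkin::FEATURE_NAMES
  # put signal in three canonical features
  tab$mean_amplitude <- -sep * scores + rnorm(n)
  tab$mean_speed <- -sep * scores + rnorm(n)
  tab$cv_amplitude <- sep * (scores >= 2) + rnorm(n)
  tab$age <- rnorm(n, 63, 8)
  tab$sex <- sample(c("F", "M"), n, replace = TRUE)
  tab$score <- scores
  tab$is_control <- scores == 0
  tab
}

tmp_path <- function(ext = "") {
  tempfile(pattern = "tapkin-test-", fileext = ext)
}
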