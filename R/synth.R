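# Synthetic tapping-signal generator: a stated world for end-to-end testing.
#
# A trial is a train of raised-cosine open/close cycles on a 5 degree closed
# baseline. Cycle k has amplitude A_k (lognormal-free: truncated normal draw
# around the target mean, then a deterministic linear trend so the realized
# first-half/second-half amplitude ratio hits decay_ratio in expectation) and
# duration D_k (truncated normal around the target). The trace starts on a
# half-closing and ends on a half-opening so every one of the n_taps peaks is
# flanked by interior valleys: segmentation recovers exactly n_taps taps.

BASELINE_DEG <- 5

#' Parameters of a synthetic tapping trial
#'
#' @param n_taps Number of complete taps (>= 2).
#' @param mean_peak_to_valley Target mean tap amplitude, degrees.
#' @param amplitude_cv Cycle-to-cycle amplitude coefficient of variation.
#' @param mean_cycle_duration Target mean cycle duration, seconds.
#' @param cycle_duration_cv Cycle-duration coefficient of variation.
#' @param opening_fraction Share of each cycle spent opening, in (0, 1).
#' @param decay_ratio Target first-half / second-half amplitude ratio
#'   (sequence effect; 1 = no decay).
#' @param noise_sd Additive Gaussian measurement noise, degrees.
#' @param frame_rate Sampling rate, Hz.
#' @param seed Integer RNG seed.
#' @return An object of class `tap_signal_params`.
#' @export
tap_signal_params <- function(n_taps = 30L, mean_peak_to_valley = 36.81,
                              amplitude_cv = 0.17, mean_cycle_duration = 0.44,
                              cycle_duration_cv = 0.12, opening_fraction = 0.5,
                              decay_ratio = 1.02, noise_sd = 0.5,
                              frame_rate = 30, seed = 1L) {
  tk_assert(is_count(n_taps) && n_taps >= 2,
            "n_taps must be an integer >= 2", "tk_invalid_parameter_error")
  for (nm in c("mean_peak_to_valley", "mean_cycle_duration", "frame_rate")) {
    v <- get(nm)
    tk_assert(is_scalar_num(v) && v > 0, sprintf("%s must be > 0", nm),
              "tk_invalid_parameter_error")
  }
  tk_assert(is_scalar_num(amplitude_cv) && amplitude_cv >= 0,
            "amplitude_cv must be >= 0", "tk_invalid_parameter_error")
  tk_assert(is_scalar_num(cycle_duration_cv) && cycle_duration_cv >= 0,
            "cycle_duration_cv must be >= 0", "tk_invalid_parameter_error")
  tk_assert(is_scalar_num(opening_fraction) && opening_fraction > 0 &&
              opening_fraction < 1,
            "opening_fraction must lie in (0, 1)", "tk_invalid_parameter_error")
  tk_assert(is_scalar_num(decay_ratio) && decay_ratio > 0,
            "decay_ratio must be > 0", "tk_invalid_parameter_error")
  tk_assert(is_scalar_num(noise_sd) && noise_sd >= 0,
            "noise_sd must be >= 0", "tk_invalid_parameter_error")
  structure(list(n_taps = as.integer(n_taps),
                 mean_peak_to_valley = mean_peak_to_valley,
                 amplitude_cv = amplitude_cv,
                 mean_cycle_duration = mean_cycle_duration,
                 cycle_duration_cv = cycle_duration_cv,
                 opening_fraction = opening_fraction,
                 decay_ratio = decay_ratio, noise_sd = noise_sd,
                 frame_rate = frame_rate, seed = as.integer(seed)),
            class = "tap_signal_params")
}

# Linear trend multipliers m_k (mean 1) whose first-half / second-half means
# have ratio r exactly.
decay_trend <- function(n, r) {
  h <- floor(n / 2)
  d1 <- (1 + h) / 2 - (n + 1) / 2
  d2 <- (h + 1 + n) / 2 - (n + 1) / 2
  s <- (r - 1) / (d1 - r * d2)
  1 + s * (seq_len(n) - (n + 1) / 2)
}

#' Severity presets for the synthetic generator
#'
#' One preset per clinical finger-tapping score 0-3. Within-trial targets
#' (amplitude and cycle-duration means and CVs, amplitude decay) follow the
#' published per-score group means for video-derived tapping features;
#' opening_fraction is set from the relative opening/closing speeds. The
#' `between_sd` entry carries the corresponding between-subject SDs, used
#' (scaled) by [simulate_cohort()] to spread subject-level parameters.
#'
#' @return Named list of `severity_preset` objects keyed `"0" .. "3"`, each
#'   with fields `score`, `params` ([tap_signal_params()]), `between_sd`.
#' @export
severity_presets <- function() {
  tab <- data.frame(
    score = 0:3,
    amp = c(36.81, 32.86, 31.04, 26.87),
    amp_sd = c(18.96, 12.95, 26.87, 87.99),
    cv_amp = c(0.17, 0.15, 0.21, 0.28),
    cv_amp_sd = c(0.10, 0.10, 0.10, 0.12),
    dur = c(0.44, 0.33, 0.37, 0.37),
    dur_sd = c(0.17, 0.12, 0.16, 0.16),
    cv_dur = c(0.12, 0.08, 0.14, 0.24),
    cv_dur_sd = c(0.09, 0.02, 0.09, 0.16),
    decay = c(1.02, 1.13, 1.23, 1.20),
    decay_sd = c(0.10, 0.16, 0.32, 1.36),
    open_speed = c(185.23, 186.04, 163.72, 147.40),
    close_speed = c(187.73, 197.93, 183.96, 159.67)
  )
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    structure(list(
      score = r$score,
      params = tap_signal_params(
        n_taps = 30L,
        mean_peak_to_valley = r$amp, amplitude_cv = r$cv_amp,
        mean_cycle_duration = r$dur, cycle_duration_cv = r$cv_dur,
        opening_fraction = r$close_speed / (r$open_speed + r$close_speed),
        decay_ratio = r$decay, noise_sd = 0.5, frame_rate = 30, seed = 1L),
      between_sd = list(mean_peak_to_valley = r$amp_sd,
                        amplitude_cv = r$cv_amp_sd,
                        mean_cycle_duration = r$dur_sd,
                        cycle_duration_cv = r$cv_dur_sd,
                        decay_ratio = r$decay_sd)),
      class = "severity_preset")
  })
  names(out) <- as.character(tab$score)
  out
}

#' Simulate a synthetic tapping displacement signal
#'
#' @param params A [tap_signal_params()].
#' @return A raw (unfiltered) [displacement_signal()]. The attribute `truth`
#'   holds the generating per-tap amplitudes `A`, durations `D`, and exact
#'   valley/peak times.
#' @export
simulate_signal <- function(params) {
  tk_assert(inherits(params, "tap_signal_params"),
            "params must be a tap_signal_params object",
            "tk_invalid_parameter_error")
  p <- params
  n <- p$n_taps
  with_seed(p$seed, {
    A <- stats::rnorm(n, p$mean_peak_to_valley,
                      p$amplitude_cv * p$mean_peak_to_valley)
    A <- pmax(A, 0.1 * p$mean_peak_to_valley)
    A <- A * decay_trend(n, p$decay_ratio)
    D <- stats::rnorm(n, p$mean_cycle_duration,
                      p$cycle_duration_cv * p$mean_cycle_duration)
    D <- pmax(D, 0.2 * p$mean_cycle_duration)
    f <- p$opening_fraction
    lead_in <- (1 - f) * p$mean_cycle_duration   # half-closing from a peak
    lead_out <- f * p$mean_cycle_duration        # half-opening to a peak
    valley_t <- lead_in + c(0, cumsum(D))        # v_1 .. v_(n+1)
    peak_t <- valley_t[seq_len(n)] + f * D
    total <- lead_in + sum(D) + lead_out
    tt <- seq(0, total, by = 1 / p$frame_rate)
    y <- numeric(length(tt))
    # lead-in: closing half-cosine from BASELINE + A_1 down to the baseline
    seg <- tt < valley_t[1]
    y[seg] <- BASELINE_DEG + A[1] * (1 + cos(pi * tt[seg] / lead_in)) / 2
    for (k in seq_len(n)) {
      t0 <- valley_t[k]; tp <- peak_t[k]; t1 <- valley_t[k + 1]
      seg <- tt >= t0 & tt < tp
      y[seg] <- BASELINE_DEG +
        A[k] * (1 - cos(pi * (tt[seg] - t0) / (tp - t0))) / 2
      seg <- tt >= tp & tt < t1
      y[seg] <- BASELINE_DEG +
        A[k] * (1 + cos(pi * (tt[seg] - tp) / (t1 - tp))) / 2
    }
    # lead-out: opening half-cosine toward BASELINE + A_n
    seg <- tt >= valley_t[n + 1]
    y[seg] <- BASELINE_DEG +
      A[n] * (1 - cos(pi * pmin(tt[seg] - valley_t[n + 1], lead_out) /
                        lead_out)) / 2
    if (p$noise_sd > 0) y <- y + stats::rnorm(length(y), 0, p$noise_sd)
    sig <- displacement_signal(y, p$frame_rate, filtered = FALSE,
                               source = "simulate_signal")
    attr(sig, "truth") <- list(A = A, D = D, valley_t = valley_t,
                               peak_t = peak_t, params = p)
    sig
  })
}

# Constant 21-landmark hand template (wrist at origin, x toward the index
# finger, units arbitrary); only wrist/thumb-tip/index-tip are used downstream.
hand_template <- function() {
  tpl <- matrix(0, nrow = N_LANDMARKS, ncol = 3)
  tpl[2:4, ] <- cbind(c(0.05, 0.10, 0.16), c(0.05, 0.10, 0.14), 0) # thumb chain
  tpl[6:8, ] <- cbind(c(0.18, 0.25, 0.31), c(0.01, 0.01, 0.01), 0) # index chain
  tpl[10:13, ] <- cbind(c(0.17, 0.25, 0.31, 0.36), -0.02, 0)       # middle
  tpl[14:17, ] <- cbind(c(0.16, 0.23, 0.29, 0.33), -0.06, 0)       # ring
  tpl[18:21, ] <- cbind(c(0.15, 0.20, 0.25, 0.28), -0.10, 0)       # little
  tpl
}

#' Project a displacement signal to a synthetic 21-landmark stream
#'
#' Inverse of [compute_angle_signal()]: the wrist sits at the origin, the
#' index base-to-tip vector is fixed, and the thumb tip is rotated so the
#' angle between the two base-to-tip vectors equals the signal at every frame.
#' The remaining 18 landmarks are plausible constants (unused downstream).
#'
#' @param signal A [displacement_signal()] with angles in \[0, 180) degrees.
#' @return A [landmark_sequence()] at the signal's frame rate.
#' @export
signal_to_landmarks <- function(signal) {
  ang <- signal$values
  tk_assert(all(ang >= 0 & ang < 180),
            "angles must lie in [0, 180) degrees", "tk_range_error")
  n <- length(ang)
  tpl <- hand_template()
  coords <- array(rep(tpl, each = n), dim = c(n, N_LANDMARKS, 3))
  index_len <- 0.35
  thumb_len <- 0.25
  coords[, LANDMARK_INDEX[["index_tip"]] + 1L, ] <-
    matrix(rep(c(index_len, 0, 0), each = n), nrow = n)
  th <- ang * pi / 180
  coords[, LANDMARK_INDEX[["thumb_tip"]] + 1L, ] <-
    cbind(thumb_len * cos(th), thumb_len * sin(th), 0)
  landmark_sequence(coords, signal$frame_rate)
}

# Truncated-normal draw via clamping (documented approximation; the clamp is
# only active in far tails for default settings).
draw_trunc <- function(n, mean, sd, lo, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate a labeled feature cohort
#'
#' For each requested severity class, draws per-subject trial parameters
#' around the class preset (between-subject SDs scaled by
#' `feature_noise_scale`), simulates the angle trace, runs the full
#' filter/segment/feature pipeline, and attaches age, sex, score, and the
#' healthy-control flag (`is_control` is `score == 0`, as in cohorts where
#' all score-0 recordings come from controls).
#'
#' @param n_per_class Subjects per class (>= 2).
#' @param presets Named list from [severity_presets()] (or a subset).
#' @param feature_noise_scale Multiplier on the between-subject SDs
#'   (default 1; 0.25 gives a shrunken-spread cohort).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param scores Severity scores to include (default: all preset keys).
#' @return Feature table (data frame) with [FEATURE_TABLE_COLUMNS].
#' @export
simulate_cohort <- function(n_per_class, presets = severity_presets(),
                            feature_noise_scale = 1, seed = 1L,
                            scores = as.integer(names(presets))) {
  tk_assert(is_count(n_per_class) && n_per_class >= 2,
            "n_per_class must be an integer >= 2", "tk_invalid_parameter_error")
  missing <- setdiff(as.character(scores), names(presets))
  tk_assert(length(missing) == 0,
            sprintf("no preset for requested score(s): %s",
                    paste(missing, collapse = ", ")), "tk_config_error")
  n_total <- n_per_class * length(scores)
  seeds <- derive_seeds(seed, 2L * n_total + 1L)
  rows <- vector("list", n_total)
  i <- 0L
  for (s in scores) {
    pre <- presets[[as.character(s)]]
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      subj <- with_seed(seeds[i], {
        b <- lapply(pre$between_sd, function(x) x * feature_noise_scale)
        p0 <- pre$params
        list(
          amp = draw_trunc(1, p0$mean_peak_to_valley, b$mean_peak_to_valley,
                           0.25 * p0$mean_peak_to_valley),
          cv_amp = draw_trunc(1, p0$amplitude_cv, b$amplitude_cv, 0.01, 0.6),
          dur = draw_trunc(1, p0$mean_cycle_duration, b$mean_cycle_duration,
                           0.15, 1.5),
          cv_dur = draw_trunc(1, p0$cycle_duration_cv, b$cycle_duration_cv,
                              0.01, 0.6),
          decay = draw_trunc(1, p0$decay_ratio, b$decay_ratio, 0.6, 2.5),
          age = stats::rnorm(1, if (s == 0) 62.7 else 63.5,
                             if (s == 0) 8.1 else 7.8),
          sex = sample(c("F", "M"), 1L)
        )
      })
      params <- tap_signal_params(
        n_taps = pre$params$n_taps,
        mean_peak_to_valley = subj$amp, amplitude_cv = subj$cv_amp,
        mean_cycle_duration = subj$dur, cycle_duration_cv = subj$cv_dur,
        opening_fraction = pre$params$opening_fraction,
        decay_ratio = subj$decay, noise_sd = pre$params$noise_sd,
        frame_rate = pre$params$frame_rate,
        seed = seeds[n_total + i])
      feats <- cohort_features(params)
      feats$age <- subj$age
      feats$sex <- subj$sex
      feats$score <- s
      feats$is_control <- s == 0
      rows[[i]] <- feats
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# One subject's features, with a deterministic re-draw guard for the rare
# seed where noise breaks segmentation.
cohort_features <- function(params) {
  for (attempt in 0:4) {
    p <- params
    p$seed <- as.integer((params$seed + attempt * 7919L) %% .Machine$integer.max)
    res <- tryCatch({
      sig <- lowpass(simulate_signal(p))
      extract_features(sig, segment_cycles(sig))
    }, tapkin_error = function(e) e)
    if (!inherits(res, "error")) return(res)
  }
  stop(res)
}
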