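# Landmarks -> angular displacement -> filtered signal -> tapping cycles.

#' Low-pass filter configuration
#'
#' @param cutoff Cut-off frequency in Hz (default 7, the value used for
#'   finger-tapping angle traces; tapping fundamentals sit at 2-4 Hz).
#' @param order Butterworth order (default 4).
#' @param zero_phase Apply forward-backward (zero-phase) filtering so event
#'   timing is preserved (default `TRUE`).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(cutoff = 7, order = 4L, zero_phase = TRUE) {
  tk_assert(is_scalar_num(cutoff) && cutoff > 0, "cutoff must be > 0",
            "tk_config_error")
  tk_assert(is_count(order) && order >= 1, "order must be a positive integer",
            "tk_config_error")
  structure(list(cutoff = cutoff, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_config")
}

#' Thumb-index opening angle from hand landmarks
#'
#' Per frame, with b = wrist, t = thumb tip, i = index tip:
#' v1 = t - b, v2 = i - b, angle = acos( v1.v2 / (|v1| |v2|) ) in degrees,
#' the cosine argument clamped to \[-1, 1\]. Invariant to translation,
#' rotation and uniform scaling of the landmarks.
#'
#' @param seq A fully observed [landmark_sequence()] (run [fill_gaps()] first).
#' @return An unfiltered [displacement_signal()].
#' @export
compute_angle_signal <- function(seq) {
  tk_assert(all(seq$mask),
            "sequence has masked frames; run fill_gaps() first",
            "tk_masked_frames_error")
  base <- seq$coords[, LANDMARK_INDEX[["wrist"]] + 1L, , drop = FALSE]
  v1 <- seq$coords[, LANDMARK_INDEX[["thumb_tip"]] + 1L, , drop = FALSE] - base
  v2 <- seq$coords[, LANDMARK_INDEX[["index_tip"]] + 1L, , drop = FALSE] - base
  v1 <- matrix(v1, ncol = 3L)
  v2 <- matrix(v2, ncol = 3L)
  n1 <- sqrt(rowSums(v1^2))
  n2 <- sqrt(rowSums(v2^2))
  bad <- which(n1 == 0 | n2 == 0)
  if (length(bad) > 0) {
    tk_stop(sprintf("degenerate geometry: fingertip coincides with hand base at frame %d",
                    bad[1]), "tk_degenerate_geometry_error")
  }
  cosang <- pmin(1, pmax(-1, rowSums(v1 * v2) / (n1 * n2)))
  displacement_signal(acos(cosang) * 180 / pi, seq$frame_rate,
                      filtered = FALSE, source = "landmarks")
}

# --- Butterworth low-pass via bilinear transform -----------------------------

# Returns list(b, a) for a digital Butterworth low-pass. DC gain is exactly 1.
butter_lowpass <- function(cutoff, fs, order) {
  Wn <- cutoff / (fs / 2)
  tk_assert(Wn > 0 && Wn < 1, "cutoff must lie strictly below Nyquist",
            "tk_config_error")
  # analog prototype poles on the unit circle, scaled by the prewarped cutoff
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  warped <- 4 * tan(pi * Wn / 2)          # fs normalized to 2
  p <- warped * p_proto
  zd <- (4 + p) / (4 - p)                 # bilinear: s = 4 (1-z^-1)/(1+z^-1)
  poly_from_roots <- function(r) {
    cf <- 1
    for (root in r) cf <- c(cf, 0) - c(0, cf * root)
    cf
  }
  a <- Re(poly_from_roots(zd))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b)                # unit DC gain
  list(b = b, a = a)
}

# Direct-form-II-transposed IIR filter, zero initial state.
iir_filter <- function(b, a, x) {
  n <- length(x)
  nb <- length(b)
  na <- length(a)
  m <- max(nb, na)
  b <- c(b, rep(0, m - nb)) / a[1]
  a <- c(a, rep(0, m - na)) / a[1]
  y <- numeric(n)
  z <- numeric(m - 1)
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (m > 2) {
      z[1:(m - 2)] <- b[2:(m - 1)] * xi + z[2:(m - 1)] - a[2:(m - 1)] * yi
    }
    z[m - 1] <- b[m] * xi - a[m] * yi
    y[i] <- yi
  }
  y
}

# Zero-phase filtering with odd-reflection padding at both ends.
filtfilt_odd <- function(b, a, x) {
  n <- length(x)
  padlen <- min(n - 1L, max(3L * (max(length(a), length(b)) - 1L), 60L))
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  ext <- c(pre, x, post)
  y <- iir_filter(b, a, ext)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

# Squared-magnitude response of the zero-phase digital Butterworth at f Hz;
# analytic, used as the test oracle for attenuation.
butter_zero_phase_gain <- function(f, cutoff, fs, order) {
  ratio <- tan(pi * f / fs) / tan(pi * cutoff / fs)
  1 / (1 + ratio^(2 * order))
}

#' Zero-phase low-pass filter a displacement signal
#'
#' Order-`cfg$order` Butterworth applied forward then backward (zero phase,
#' squared magnitude response), so peak and valley timing is not shifted.
#'
#' @param signal An unfiltered [displacement_signal()].
#' @param cfg A [filter_config()].
#' @return The filtered [displacement_signal()] (same length).
#' @export
lowpass <- function(signal, cfg = filter_config()) {
  tk_assert(inherits(signal, "displacement_signal"), "not a displacement_signal",
            "tk_schema_error")
  tk_assert(!signal$filtered, "signal is already filtered", "tk_config_error")
  tk_assert(cfg$cutoff < signal$frame_rate / 2,
            "cutoff must be below the Nyquist frequency", "tk_config_error")
  tk_assert(length(signal$values) > 3L * cfg$order,
            "signal too short for the requested filter order", "tk_schema_error")
  ba <- butter_lowpass(cfg$cutoff, signal$frame_rate, cfg$order)
  y <- if (cfg$zero_phase) {
    filtfilt_odd(ba$b, ba$a, signal$values)
  } else {
    iir_filter(ba$b, ba$a, signal$values)
  }
  out <- displacement_signal(y, signal$frame_rate, filtered = TRUE,
                             source = signal$source)
  out
}

# --- peak / valley detection -------------------------------------------------

# Strict interior local maxima.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

# Topographic prominence of each candidate peak.
peak_prominence <- function(x, idx) {
  vapply(idx, function(i) {
    lmin <- x[i]
    j <- i - 1L
    while (j >= 1L && x[j] <= x[i]) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    left <- lmin
    rmin <- x[i]
    j <- i + 1L
    n <- length(x)
    while (j <= n && x[j] <= x[i]) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    x[i] - max(left, rmin)
  }, numeric(1))
}

# Peaks with prominence and minimum-separation constraints; higher-prominence
# peaks win separation conflicts.
find_peaks <- function(x, min_prom, min_dist) {
  idx <- local_maxima(x)
  if (length(idx) == 0L) return(integer(0))
  prom <- peak_prominence(x, idx)
  keep <- prom >= min_prom
  idx <- idx[keep]
  prom <- prom[keep]
  if (length(idx) <= 1L) return(idx)
  ord <- order(-prom, idx)
  sel <- logical(length(x))
  chosen <- integer(0)
  for (i in ord) {
    p <- idx[i]
    if (length(chosen) == 0L || all(abs(chosen - p) >= min_dist)) {
      chosen <- c(chosen, p)
    }
  }
  sort(chosen)
}

#' Segment tapping cycles from a filtered displacement signal
#'
#' Peaks are maximum finger openings, valleys maximum closures. Events must
#' exceed a prominence threshold expressed as a fraction of the robust signal
#' range (95th minus 5th percentile) and be separated by at least
#' `min_separation` seconds. Alternation is enforced by keeping, between
#' consecutive peaks, the single lowest valley (and between consecutive
#' valleys, the single highest peak). Leading/trailing partial cycles are
#' dropped so each tap is a complete valley-peak-valley triplet.
#'
#' @param signal A filtered [displacement_signal()].
#' @param min_prominence_frac Prominence threshold as a fraction of the robust
#'   range (default 0.1).
#' @param min_separation Minimum event separation in seconds (default 0.1; a
#'   4 Hz rhythm, the fastest plausible tapping, is never merged).
#' @return An object of class `cycle_segmentation` with `valley_indices`,
#'   `peak_indices`, and a per-tap data frame `taps` (columns `valley`,
#'   `peak`, `next_valley`, 1-based frame indices).
#' @export
segment_cycles <- function(signal, min_prominence_frac = 0.1,
                           min_separation = 0.1) {
  tk_assert(inherits(signal, "displacement_signal"), "not a displacement_signal",
            "tk_schema_error")
  tk_assert(signal$filtered, "segment_cycles expects a filtered signal",
            "tk_config_error")
  x <- signal$values
  rng <- diff(stats::quantile(x, c(0.05, 0.95), names = FALSE))
  min_prom <- min_prominence_frac * rng
  min_dist <- min_separation * signal$frame_rate
  peaks <- find_peaks(x, min_prom, min_dist)
  valleys <- find_peaks(-x, min_prom, min_dist)
  if (length(peaks) < 2L || length(valleys) < 2L) {
    tk_stop("insufficient movement: fewer than 2 complete taps detected",
            "tk_insufficient_movement_error")
  }
  # enforce strict alternation: collapse runs of same-type events
  ev <- data.frame(idx = c(peaks, valleys),
                   type = rep(c("p", "v"), c(length(peaks), length(valleys))))
  ev <- ev[order(ev$idx), ]
  out_idx <- integer(0)
  out_type <- character(0)
  for (i in seq_len(nrow(ev))) {
    if (length(out_type) > 0 && out_type[length(out_type)] == ev$type[i]) {
      last <- out_idx[length(out_idx)]
      cur <- ev$idx[i]
      better <- if (ev$type[i] == "p") x[cur] > x[last] else x[cur] < x[last]
      if (better) out_idx[length(out_idx)] <- cur
    } else {
      out_idx <- c(out_idx, ev$idx[i])
      out_type <- c(out_type, ev$type[i])
    }
  }
  # trim so the series starts and ends with a valley
  while (length(out_type) > 0 && out_type[1] == "p") {
    out_idx <- out_idx[-1]; out_type <- out_type[-1]
  }
  while (length(out_type) > 0 && out_type[length(out_type)] == "p") {
    out_idx <- out_idx[-length(out_idx)]; out_type <- out_type[-length(out_type)]
  }
  pk <- out_idx[out_type == "p"]
  vl <- out_idx[out_type == "v"]
  if (length(pk) < 2L) {
    tk_stop("insufficient movement: fewer than 2 complete taps detected",
            "tk_insufficient_movement_error")
  }
  taps <- data.frame(valley = vl[seq_along(pk)], peak = pk,
                     next_valley = vl[seq_along(pk) + 1L])
  structure(list(valley_indices = vl, peak_indices = pk, taps = taps),
            class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("<cycle_segmentation> %d taps (%d valleys, %d peaks)\n",
              nrow(x$taps), length(x$valley_indices), length(x$peak_indices)))
  invisible(x)
}
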