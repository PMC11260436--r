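# The 13 kinematic features computed from a segmented angle trace.

#' Canonical kinematic feature names
#'
#' Column order is fixed; downstream model feature selection tie-breaks on it.
#' @format Character vector of length 13.
#' @export
FEATURE_NAMES <- c(
  "mean_amplitude", "cv_amplitude",
  "mean_speed", "cv_speed",
  "mean_opening_speed", "cv_opening_speed",
  "mean_closing_speed", "cv_closing_speed",
  "mean_cycle_duration", "cv_cycle_duration", "range_cycle_duration",
  "rate", "amplitude_decay"
)

#' Columns of a full feature table (features plus covariates and labels)
#' @format Character vector of length 17.
#' @export
FEATURE_TABLE_COLUMNS <- c(FEATURE_NAMES, "age", "sex", "score", "is_control")

#' Extract the 13 kinematic features from a segmented signal
#'
#' Per tap k with events (valley v_k, peak p_k, valley v_(k+1)), times t():
#' amplitude `A_k = angle(p_k) - angle(v_k)`; opening duration
#' `t(p_k) - t(v_k)`; closing duration `t(v_(k+1)) - t(p_k)`; cycle duration
#' `D_k = t(v_(k+1)) - t(v_k)`; speed `A_k / D_k`; opening speed
#' `A_k /` opening duration; closing speed
#' `(angle(p_k) - angle(v_(k+1))) /` closing duration.
#' Mean and CV (sample SD / mean) are taken over taps;
#' `range_cycle_duration = max D_k - min D_k`; `rate = n_taps / (t(v_(n+1)) -
#' t(v_1))` (movement time, not file length); `amplitude_decay =
#' mean(A, first floor(n/2) taps) / mean(A, last ceiling(n/2) taps)`,
#' the sequence-effect measure (ratio > 1 means amplitude shrinks over the
#' trial). The half-split is by tap index, robust to within-trial rate change.
#'
#' @param signal The [displacement_signal()] the segmentation refers to.
#' @param seg A [segment_cycles()] result with at least 4 taps.
#' @return One-row data frame with the columns in [FEATURE_NAMES].
#' @export
extract_features <- function(signal, seg) {
  tk_assert(inherits(seg, "cycle_segmentation"), "not a cycle_segmentation",
            "tk_schema_error")
  taps <- seg$taps
  n <- nrow(taps)
  if (n < 4L) {
    tk_stop(sprintf("need >= 4 complete taps, found %d", n),
            "tk_insufficient_taps_error")
  }
  x <- signal$values
  t <- signal_times(signal)
  amp <- x[taps$peak] - x[taps$valley]
  if (any(amp <= 0)) {
    tk_stop("non-positive tap amplitude: segmentation integrity violated",
            "tk_segmentation_integrity_error")
  }
  open_dur <- t[taps$peak] - t[taps$valley]
  close_dur <- t[taps$next_valley] - t[taps$peak]
  cyc_dur <- t[taps$next_valley] - t[taps$valley]
  close_amp <- x[taps$peak] - x[taps$next_valley]
  speed <- amp / cyc_dur
  open_speed <- amp / open_dur
  close_speed <- close_amp / close_dur
  h <- floor(n / 2)
  data.frame(
    mean_amplitude = mean(amp),
    cv_amplitude = cv(amp),
    mean_speed = mean(speed),
    cv_speed = cv(speed),
    mean_opening_speed = mean(open_speed),
    cv_opening_speed = cv(open_speed),
    mean_closing_speed = mean(close_speed),
    cv_closing_speed = cv(close_speed),
    mean_cycle_duration = mean(cyc_dur),
    cv_cycle_duration = cv(cyc_dur),
    range_cycle_duration = max(cyc_dur) - min(cyc_dur),
    rate = n / (t[taps$next_valley[n]] - t[taps$valley[1]]),
    amplitude_decay = mean(amp[seq_len(h)]) / mean(amp[(h + 1):n])
  )
}

# landmark file -> features, one trial.
landmarks_to_features <- function(path, frame_rate,
                                  filter_cfg = filter_config(),
                                  min_prominence_frac = 0.1,
                                  min_separation = 0.1,
                                  max_gap = 0.5) {
  seq <- read_landmarks(path, frame_rate = frame_rate)
  segs <- fill_gaps(seq, max_gap = max_gap)
  tk_assert(length(segs) == 1L,
            "recording split at a long detection gap; analyze segments separately",
            "tk_gap_split_error")
  sig <- lowpass(compute_angle_signal(segs[[1]]), filter_cfg)
  extract_features(sig, segment_cycles(sig, min_prominence_frac, min_separation))
}

#' Batch feature extraction over landmark or signal files
#'
#' Per-file failures are contained: a failed file contributes no feature row
#' but is recorded in the `failures` attribute (file, condition class,
#' message) instead of aborting the batch.
#'
#' @param inputs Character vector of landmark CSV/JSON or displacement CSV
#'   (`time_s,angle_deg`) paths.
#' @param frame_rate Frame rate for landmark files (ignored for displacement
#'   CSVs, which carry their own time base).
#' @param filter_cfg A [filter_config()].
#' @param min_prominence_frac,min_separation Passed to [segment_cycles()].
#' @param max_gap Passed to [fill_gaps()].
#' @param out Optional path; when given the table is also written as CSV.
#' @return Data frame of feature rows with a `file` column and a `failures`
#'   attribute (data frame, possibly empty).
#' @export
batch_extract <- function(inputs, frame_rate = 30,
                          filter_cfg = filter_config(),
                          min_prominence_frac = 0.1, min_separation = 0.1,
                          max_gap = 0.5, out = NULL) {
  tk_assert(length(inputs) > 0, "no input files given", "tk_usage_error")
  rows <- list()
  fails <- list()
  for (f in inputs) {
    res <- tryCatch({
      if (grepl("\\.(csv)$", f, ignore.case = TRUE) && is_signal_csv(f)) {
        sig <- read_signal_csv(f)
        sig <- lowpass(sig, filter_cfg)
        extract_features(sig, segment_cycles(sig, min_prominence_frac,
                                             min_separation))
      } else {
        landmarks_to_features(f, frame_rate, filter_cfg,
                              min_prominence_frac, min_separation, max_gap)
      }
    }, tapkin_error = function(e) e, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(file = f, class = class(res)[1],
                   message = conditionMessage(res))
    } else {
      res$file <- f
      rows[[length(rows) + 1L]] <- res
    }
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(numeric(0), ncol = 14)),
                    c(FEATURE_NAMES, "file"))
  attr(tab, "failures") <- if (length(fails) > 0) do.call(rbind, fails) else
    data.frame(file = character(0), class = character(0),
               message = character(0))
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  tab
}

is_signal_csv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  identical(hdr, c("time_s", "angle_deg"))
}

#' Write / read a feature table with the canonical header
#'
#' @param table Data frame containing at least [FEATURE_NAMES]; `age`, `sex`,
#'   `score`, `is_control` are written when present.
#' @param path CSV path.
#' @return `path` (write) or the table (read), invisibly/visibly.
#' @export
write_feature_table <- function(table, path) {
  keep <- intersect(FEATURE_TABLE_COLUMNS, names(table))
  utils::write.csv(table[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path)
  missing <- setdiff(FEATURE_NAMES, names(df))
  tk_assert(length(missing) == 0,
            sprintf("feature table missing columns: %s",
                    paste(missing, collapse = ", ")), "tk_schema_error")
  if ("is_control" %in% names(df)) df$is_control <- as.logical(df$is_control)
  df
}
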