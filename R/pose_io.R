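# Hand-landmark and displacement-signal containers and file I/O.
#
# Landmarks follow the MediaPipe 21-point schema (0-based convention):
# 0 = wrist / hand base, 4 = thumb tip, 8 = index-finger tip. Coordinates may
# be image-normalized or metric; the downstream angle is scale-invariant so
# both are accepted.

#' MediaPipe landmark indices used by the pipeline (0-based)
#' @format Named integer vector with entries `wrist`, `thumb_tip`, `index_tip`.
#' @export
LANDMARK_INDEX <- c(wrist = 0L, thumb_tip = 4L, index_tip = 8L)

N_LANDMARKS <- 21L

#' Construct a hand-landmark sequence
#'
#' @param coords Numeric array `n_frames x 21 x 3` (use z = 0 for 2-D data).
#'   Frames where the hand was not detected hold `NA` and are masked.
#' @param frame_rate Frames per second (> 0).
#' @param mask Logical vector, `TRUE` where the frame is present. Defaults to
#'   frames with no missing coordinates.
#' @return An object of class `landmark_sequence`.
#' @export
landmark_sequence <- function(coords, frame_rate, mask = NULL) {
  tk_assert(is.array(coords) && length(dim(coords)) == 3L &&
              dim(coords)[2] == N_LANDMARKS && dim(coords)[3] == 3L,
            "coords must be an n x 21 x 3 array", "tk_schema_error")
  tk_assert(is_scalar_num(frame_rate) && frame_rate > 0,
            "frame_rate must be a positive number", "tk_schema_error")
  if (is.null(mask)) mask <- apply(coords, 1L, function(f) !anyNA(f))
  tk_assert(length(mask) == dim(coords)[1],
            "mask length must equal number of frames", "tk_schema_error")
  structure(list(coords = coords, frame_rate = frame_rate,
                 mask = as.logical(mask)),
            class = "landmark_sequence")
}

#' @export
print.landmark_sequence <- function(x, ...) {
  cat(sprintf("<landmark_sequence> %d frames @ %g FPS (%d masked)\n",
              dim(x$coords)[1], x$frame_rate, sum(!x$mask)))
  invisible(x)
}

n_frames <- function(seq) dim(seq$coords)[1]

#' Construct an angular displacement signal
#'
#' A uniformly sampled thumb-index opening angle trace in degrees.
#'
#' @param values Numeric vector of angles (degrees), length >= 2, finite.
#' @param frame_rate Sampling rate in Hz (> 0).
#' @param filtered Logical; has the low-pass filter been applied?
#' @param source Free-form provenance id.
#' @return An object of class `displacement_signal`.
#' @export
displacement_signal <- function(values, frame_rate, filtered = FALSE,
                                source = NA_character_) {
  tk_assert(is.numeric(values) && length(values) >= 2L && all(is.finite(values)),
            "signal values must be finite and of length >= 2", "tk_schema_error")
  tk_assert(is_scalar_num(frame_rate) && frame_rate > 0,
            "frame_rate must be a positive number", "tk_schema_error")
  structure(list(values = as.numeric(values), frame_rate = frame_rate,
                 filtered = isTRUE(filtered), source = source),
            class = "displacement_signal")
}

#' @export
print.displacement_signal <- function(x, ...) {
  cat(sprintf("<displacement_signal> %d samples @ %g FPS, %s\n",
              length(x$values), x$frame_rate,
              if (x$filtered) "filtered" else "raw"))
  invisible(x)
}

signal_times <- function(sig) (seq_along(sig$values) - 1) / sig$frame_rate

landmark_csv_header <- function() {
  c("frame", as.vector(t(outer(c("x", "y", "z"), 0:20,
                               function(a, b) paste0(a, b)))))
}

#' Read a hand-landmark time series
#'
#' CSV dialect: header `frame,x0,y0,z0,...,x20,y20,z20`, one row per detected
#' frame. JSON: an array of `{frame, landmarks: [[x,y,z], ...21]}` records.
#' Frame numbers absent from the file (detection gaps) become masked frames.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @param frame_rate Frames per second of the source video.
#' @return A [landmark_sequence()].
#' @export
read_landmarks <- function(path, format = c("auto", "csv", "json"), frame_rate) {
  format <- match.arg(format)
  tk_assert(file.exists(path), sprintf("file not found: %s", path),
            "tk_io_error")
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    tk_assert(identical(names(df), landmark_csv_header()),
              "landmark CSV must have header frame,x0,y0,z0,...,x20,y20,z20",
              "tk_schema_error")
    frames <- as.integer(df$frame)
    mat <- as.matrix(df[, -1, drop = FALSE])
  } else {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    tk_assert(length(recs) > 0, "empty landmark JSON", "tk_schema_error")
    frames <- vapply(recs, function(r) as.integer(r$frame), integer(1))
    mat <- t(vapply(recs, function(r) {
      lm <- r$landmarks
      tk_assert(length(lm) == N_LANDMARKS,
                sprintf("frame %d has %d landmarks, expected 21",
                        r$frame, length(lm)), "tk_schema_error")
      unlist(lapply(lm, function(p) {
        p <- as.numeric(p)
        if (length(p) == 2L) p <- c(p, 0)
        tk_assert(length(p) == 3L, "landmark must have 2 or 3 coordinates",
                  "tk_schema_error")
        p
      }))
    }, numeric(3L * N_LANDMARKS)))
  }
  tk_assert(!is.unsorted(frames, strictly = TRUE),
            "frame indices must be strictly increasing", "tk_ordering_error")
  # expand to the full frame range; absent frames are masked
  rng <- frames - frames[1] + 1L
  n <- rng[length(rng)]
  coords <- array(NA_real_, dim = c(n, N_LANDMARKS, 3L))
  for (i in seq_along(rng)) {
    coords[rng[i], , ] <- matrix(mat[i, ], nrow = N_LANDMARKS, byrow = TRUE)
  }
  landmark_sequence(coords, frame_rate)
}

#' Write a hand-landmark time series
#'
#' Masked (gap) frames are omitted from the file, mirroring what a pose
#' estimator emits when the hand is not detected.
#'
#' @param seq A [landmark_sequence()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(seq, path, format = c("csv", "json")) {
  format <- match.arg(format)
  keep <- which(seq$mask)
  if (format == "csv") {
    mat <- t(vapply(keep, function(i) as.vector(t(seq$coords[i, , ])),
                    numeric(3L * N_LANDMARKS)))
    df <- data.frame(frame = keep - 1L, mat)
    names(df) <- landmark_csv_header()
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    recs <- lapply(keep, function(i) {
      list(frame = i - 1L,
           landmarks = lapply(seq_len(N_LANDMARKS),
                              function(j) as.numeric(seq$coords[i, j, ])))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read / write a displacement signal as CSV
#'
#' Dialect: header `time_s,angle_deg`; time implied uniform.
#'
#' @param path File path.
#' @return [read_signal_csv()]: a [displacement_signal()].
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  tk_assert(identical(names(df), c("time_s", "angle_deg")),
            "displacement CSV must have header time_s,angle_deg",
            "tk_schema_error")
  dt <- diff(df$time_s)
  tk_assert(all(dt > 0), "time must be strictly increasing", "tk_ordering_error")
  tk_assert(max(dt) - min(dt) < 1e-6 * stats::median(dt) + 1e-9,
            "displacement signal must be uniformly sampled", "tk_schema_error")
  displacement_signal(df$angle_deg, 1 / stats::median(dt), source = path)
}

#' @rdname read_signal_csv
#' @param sig A [displacement_signal()].
#' @export
write_signal_csv <- function(sig, path) {
  utils::write.csv(data.frame(time_s = signal_times(sig),
                              angle_deg = sig$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Interpolate short detection gaps and split at long ones
#'
#' Gaps (runs of masked frames) no longer than `max_gap` seconds are filled by
#' per-coordinate linear interpolation between the flanking detected frames.
#' Longer gaps split the recording: each side is analyzed separately.
#' Leading/trailing masked frames are trimmed.
#'
#' @param seq A [landmark_sequence()].
#' @param max_gap Longest gap, in seconds, that is interpolated (default 0.5).
#' @return A list of fully observed [landmark_sequence()] segments (length 1
#'   when no split was needed).
#' @export
fill_gaps <- function(seq, max_gap = 0.5) {
  mask <- seq$mask
  tk_assert(any(mask), "all frames are masked", "tk_empty_signal_error")
  first <- which(mask)[1]
  last <- max(which(mask))
  coords <- seq$coords[first:last, , , drop = FALSE]
  mask <- mask[first:last]
  n <- length(mask)
  max_run <- max_gap * seq$frame_rate
  # identify masked runs
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  split_after <- integer(0)
  for (k in seq_along(r$values)) {
    if (r$values[k]) next
    run <- starts[k]:ends[k]
    if (r$lengths[k] <= max_run) {
      a <- starts[k] - 1L
      b <- ends[k] + 1L
      w <- (run - a) / (b - a)
      for (j in seq_len(N_LANDMARKS)) for (d in 1:3) {
        coords[run, j, d] <- (1 - w) * coords[a, j, d] + w * coords[b, j, d]
      }
      mask[run] <- TRUE
    } else {
      split_after <- c(split_after, starts[k] - 1L)
    }
  }
  bounds <- c(0L, split_after, n)
  segs <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[k] + 1L):bounds[k + 1L]
    idx <- idx[mask[idx]]
    if (length(idx) < 2L) next
    segs[[length(segs) + 1L]] <-
      landmark_sequence(coords[idx, , , drop = FALSE], seq$frame_rate)
  }
  tk_assert(length(segs) >= 1L, "no usable segment after gap handling",
            "tk_empty_signal_error")
  segs
}
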