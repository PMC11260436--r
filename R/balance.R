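# Class balancing: under-sample majorities to the median class count, then
# SMOTE-interpolate minorities up to it. Applied to *training* rows only by
# the model-fitting code (doing it before the split would leak synthetic
# copies of training points into the test set).

#' Balance class counts by under-sampling and SMOTE
#'
#' Majority classes are randomly under-sampled to the median original class
#' count; minority classes are over-sampled to it with SMOTE: each synthetic
#' row is a uniform interpolation between a class member and one of its
#' k = min(5, class size - 1) nearest same-class neighbors (Euclidean
#' distance over `feature_cols`).
#'
#' @param table Data frame with a label column and numeric feature columns.
#' @param label_col Name of the class-label column (default `"score"`).
#' @param feature_cols Numeric columns defining the SMOTE feature space
#'   (default: all numeric columns except the label).
#' @param seed Integer seed; deterministic output.
#' @return Balanced data frame; synthetic rows carry `synthetic = TRUE` in
#'   the `origin` attribute data frame (parent indices and gap).
#' @export
balance_classes <- function(table, label_col = "score", feature_cols = NULL,
                            seed = 1L) {
  tk_assert(label_col %in% names(table), "label column not found",
            "tk_usage_error")
  y <- table[[label_col]]
  counts <- table(y)
  tk_assert(length(counts) >= 2, "need at least 2 classes", "tk_usage_error")
  if (any(counts < 2)) {
    tk_stop("cannot synthesize: a class has fewer than 2 rows",
            "tk_cannot_synthesize_error")
  }
  if (is.null(feature_cols)) {
    feature_cols <- names(table)[vapply(table, is.numeric, logical(1))]
    feature_cols <- setdiff(feature_cols, label_col)
  }
  target <- as.integer(round(stats::median(counts)))
  with_seed(seed, {
    pieces <- list()
    origin <- list()
    for (cl in names(counts)) {
      idx <- which(y == cl)
      n_c <- length(idx)
      if (n_c >= target) {
        keep <- if (n_c == target) idx else sort(sample(idx, target))
        pieces[[cl]] <- table[keep, , drop = FALSE]
        origin[[cl]] <- data.frame(synthetic = rep(FALSE, target),
                                   parent_a = keep, parent_b = NA_integer_,
                                   gap = NA_real_)
      } else {
        X <- as.matrix(table[idx, feature_cols, drop = FALSE])
        k <- min(5L, n_c - 1L)
        d <- as.matrix(stats::dist(X))
        diag(d) <- Inf
        nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
        need <- target - n_c
        base_pick <- sample.int(n_c, need, replace = TRUE)
        synth <- table[idx[base_pick], , drop = FALSE]
        pa <- integer(need); pb <- integer(need); gp <- numeric(need)
        for (m in seq_len(need)) {
          b <- base_pick[m]
          nb <- nn[b, sample.int(k, 1L)]
          u <- stats::runif(1)
          synth[m, feature_cols] <- (1 - u) * X[b, ] + u * X[nb, ]
          pa[m] <- idx[b]; pb[m] <- idx[nb]; gp[m] <- u
        }
        pieces[[cl]] <- rbind(table[idx, , drop = FALSE], synth)
        origin[[cl]] <- data.frame(
          synthetic = c(rep(FALSE, n_c), rep(TRUE, need)),
          parent_a = c(idx, pa), parent_b = c(rep(NA_integer_, n_c), pb),
          gap = c(rep(NA_real_, n_c), gp))
      }
    }
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    attr(out, "origin") <- do.call(rbind, c(origin, make.row.names = FALSE))
    out
  })
}
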