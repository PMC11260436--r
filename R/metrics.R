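# Classification metrics: confusion matrix, precision/recall/f1, PR-AUC.

#' Confusion matrix with fixed class levels
#'
#' Rows are truth, columns predictions; rows sum to class counts.
#'
#' @param truth,pred Vectors of equal length.
#' @param levels Class levels (default: union, sorted).
#' @return Integer matrix.
#' @export
confusion_matrix <- function(truth, pred,
                             levels = sort(unique(c(truth, pred)))) {
  tk_assert(length(truth) == length(pred),
            "truth and pred must have equal length", "tk_usage_error")
  tab <- table(factor(truth, levels = levels), factor(pred, levels = levels))
  m <- matrix(as.integer(tab), nrow = length(levels),
              dimnames = list(truth = as.character(levels),
                              pred = as.character(levels)))
  m
}

#' Precision, recall and f1 for a binary prediction
#'
#' `positive` names the positive class. f1 = 2PR / (P + R); 0 when both
#' precision and recall are 0 (no true positives).
#'
#' @param truth,pred Vectors of equal length.
#' @param positive The positive class value.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
binary_prf <- function(truth, pred, positive = TRUE) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Macro f1 over classes
#' @inheritParams confusion_matrix
#' @return Mean one-vs-rest f1 across `levels`.
#' @export
macro_f1 <- function(truth, pred, levels = sort(unique(truth))) {
  mean(vapply(levels, function(l) binary_prf(truth == l, pred == l)[["f1"]],
              numeric(1)))
}

#' Per-class accuracy (class-wise recall)
#' @inheritParams confusion_matrix
#' @return Named numeric vector, one recall per truth class.
#' @export
per_class_accuracy <- function(truth, pred, levels = sort(unique(truth))) {
  vapply(stats::setNames(levels, as.character(levels)), function(l) {
    idx <- truth == l
    if (!any(idx)) return(NA_real_)
    mean(pred[idx] == l)
  }, numeric(1))
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision summation: AP = sum_k (R_k - R_(k-1)) P_k over
#' descending score thresholds, with ties handled as a single threshold.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param truth Logical (or coercible) positive indicator.
#' @return AP in \[0, 1\].
#' @export
pr_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  tk_assert(any(truth) && any(!truth),
            "PR-AUC undefined: test labels contain a single class",
            "tk_undefined_metric_error")
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(truth)
  ap <- 0
  prev_rec <- 0
  tp <- 0
  npred <- 0
  ord <- order(-scores)
  s <- scores[ord]
  y <- truth[ord]
  i <- 1L
  n <- length(s)
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    tp <- tp + sum(y[i:j])
    npred <- npred + (j - i + 1L)
    prec <- tp / npred
    rec <- tp / npos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
    i <- j + 1L
  }
  ap
}
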