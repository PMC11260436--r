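# Severity prediction: L2-penalized logistic models arranged as a multiclass
# baseline, cumulative ordinal dichotomies, or the tiered cascade
# (control vs PD -> score 1 vs {2,3} -> score 2 vs 3), with train-only
# z-scoring, SMOTE balancing, and recursive feature elimination.

#' Train/test split and cross-validation protocol
#'
#' @param test_fraction Held-out fraction (default 0.3, i.e. 70/30).
#' @param n_folds Cross-validation folds (default 5).
#' @param stratified Stratify split and folds by class (default `TRUE`).
#' @param seed Integer seed controlling split, balancing and selection.
#' @return An object of class `split_protocol`.
#' @export
split_protocol <- function(test_fraction = 0.3, n_folds = 5L,
                           stratified = TRUE, seed = 1L) {
  tk_assert(is_scalar_num(test_fraction) && test_fraction > 0 &&
              test_fraction < 1, "test_fraction must be in (0, 1)",
            "tk_config_error")
  tk_assert(is_count(n_folds) && n_folds >= 2, "n_folds must be >= 2",
            "tk_config_error")
  structure(list(test_fraction = test_fraction, n_folds = as.integer(n_folds),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "split_protocol")
}

# --- ridge logistic regression (IRLS) ---------------------------------------

# Binary L2 logistic; penalty lambda on coefficients, not the intercept.
ridge_logistic <- function(X, y, lambda = 1, max_iter = 100L, tol = 1e-9) {
  X1 <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  y <- as.numeric(y)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X1 * w)
    beta_new <- solve(XtW %*% X1 + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  stats::setNames(drop(beta), colnames(X1))
}

logit_prob <- function(beta, X) {
  stats::plogis(drop(cbind(1, X[, names(beta)[-1], drop = FALSE]) %*% beta))
}

# Fit for 2 classes: single binary model (positive = last level); for > 2:
# one-vs-rest set of binary models.
fit_logit_model <- function(X, y, lambda = 1) {
  lev <- sort(unique(y))
  tk_assert(length(lev) >= 2, "single-class training data",
            "tk_tier_degeneracy_error")
  if (length(lev) == 2L) {
    beta <- ridge_logistic(X, y == lev[2L], lambda)
    structure(list(type = "binary", levels = lev, beta = beta),
              class = "tk_logit")
  } else {
    betas <- lapply(lev, function(l) ridge_logistic(X, y == l, lambda))
    names(betas) <- as.character(lev)
    structure(list(type = "ovr", levels = lev, betas = betas),
              class = "tk_logit")
  }
}

# Probability of the positive class (binary) or class-probability matrix (ovr).
predict_logit <- function(model, X) {
  if (model$type == "binary") {
    logit_prob(model$beta, X)
  } else {
    p <- vapply(model$betas, function(b) logit_prob(b, X), numeric(nrow(X)))
    p <- matrix(p, nrow = nrow(X), dimnames = list(NULL, names(model$betas)))
    p / rowSums(p)
  }
}

# Hard class labels at threshold 0.5 (binary; ties go to the lower class)
# or argmax (ovr).
classify_logit <- function(model, X) {
  if (model$type == "binary") {
    model$levels[ifelse(predict_logit(model, X) > 0.5, 2L, 1L)]
  } else {
    p <- predict_logit(model, X)
    model$levels[max.col(p, ties.method = "first")]
  }
}

# Mean |coefficient| per feature across constituent models (RFE influence).
logit_coef_magnitude <- function(model) {
  if (model$type == "binary") {
    abs(model$beta[-1])
  } else {
    rowMeans(vapply(model$betas, function(b) abs(b[-1]),
                    numeric(length(model$betas[[1]]) - 1L)))
  }
}

# --- splitting --------------------------------------------------------------

#' Stratified train/test split
#'
#' @param y Class labels.
#' @param test_fraction Held-out fraction.
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test`.
#' @export
stratified_split <- function(y, test_fraction, seed) {
  with_seed(seed, {
    test <- integer(0)
    for (l in sort(unique(y))) {
      idx <- which(y == l)
      n_test <- max(1L, round(length(idx) * test_fraction))
      test <- c(test, sample(idx, n_test))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(y), test), test = test)
  })
}

# Stratified k-fold assignment; returns a fold id per observation.
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (l in sort(unique(y))) {
      idx <- sample(which(y == l))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Mean CV f1 (binary f1 for 2 classes, macro f1 otherwise).
cv_f1 <- function(X, y, fold, lambda = 1) {
  vals <- vapply(sort(unique(fold)), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) {
      tk_stop("degenerate single-class training fold",
              "tk_stratification_error")
    }
    m <- fit_logit_model(X[tr, , drop = FALSE], y[tr], lambda)
    pred <- classify_logit(m, X[!tr, , drop = FALSE])
    lev <- sort(unique(y))
    if (length(lev) == 2L) {
      binary_prf(y[!tr], pred, positive = lev[2L])[["f1"]]
    } else {
      macro_f1(y[!tr], pred, levels = lev)
    }
  }, numeric(1))
  mean(vals)
}

#' Recursive feature elimination with cross-validated f1 stopping
#'
#' Builds the full elimination path: starting from all candidates, the
#' feature with the smallest mean absolute standardized coefficient across
#' CV folds is dropped and the model retrained, down to a single feature,
#' recording the mean CV f1 of every set along the path. The returned set is
#' the smallest one whose CV f1 is within `epsilon` of the best on the path
#' — elimination stops paying off once performance no longer improves, and
#' chance dips in a noisy fold score cannot freeze extra features in. Ties
#' in coefficient magnitude are broken by the fixed column order of `X`
#' (the later column is dropped), making selection deterministic.
#'
#' @param X Standardized numeric feature matrix (column order canonical).
#' @param y Class labels (2 or more classes).
#' @param n_folds,seed Cross-validation folds and seed.
#' @param epsilon Tolerated f1 shortfall from the path optimum
#'   (default 0.005); `Inf` always selects a single feature.
#' @param lambda Ridge penalty (default 1).
#' @return Character vector of surviving feature names (original order).
#' @export
rfe_select <- function(X, y, n_folds = 5L, seed = 1L, epsilon = 0.005,
                       lambda = 1) {
  tk_assert(ncol(X) >= 3L, "need at least 3 candidate features",
            "tk_usage_error")
  fold <- stratified_folds(y, n_folds, seed)
  canonical <- colnames(X)
  feats <- canonical
  path <- list(feats)
  scores <- cv_f1(X[, feats, drop = FALSE], y, fold, lambda)
  while (length(feats) > 1L) {
    mags <- matrix(0, nrow = length(feats), ncol = n_folds,
                   dimnames = list(feats, NULL))
    for (f in sort(unique(fold))) {
      tr <- fold != f
      m <- fit_logit_model(X[tr, feats, drop = FALSE], y[tr], lambda)
      mags[, f] <- logit_coef_magnitude(m)[feats]
    }
    mag <- rowMeans(mags)
    worst <- feats[max(which(mag <= min(mag) + 1e-12))]
    feats <- setdiff(feats, worst)
    path[[length(path) + 1L]] <- feats
    scores <- c(scores, cv_f1(X[, feats, drop = FALSE], y, fold, lambda))
  }
  keep <- if (is.infinite(epsilon)) {
    path[[length(path)]]
  } else {
    path[[max(which(scores >= max(scores) - epsilon))]]
  }
  canonical[canonical %in% keep]
}

# --- schemes ----------------------------------------------------------------

MODEL_CANDIDATES <- c(FEATURE_NAMES, "age", "sex")

scheme_models <- function(scheme) {
  switch(scheme,
    multiclass = list(
      list(name = "multiclass", subset = function(df) rep(TRUE, nrow(df)),
           label = function(df) df$score)),
    ordinal = list(
      list(name = "score0_vs_123", subset = function(df) rep(TRUE, nrow(df)),
           label = function(df) as.integer(df$score >= 1)),
      list(name = "score01_vs_23", subset = function(df) rep(TRUE, nrow(df)),
           label = function(df) as.integer(df$score >= 2)),
      list(name = "score012_vs_3", subset = function(df) rep(TRUE, nrow(df)),
           label = function(df) as.integer(df$score >= 3))),
    tiered = list(
      list(name = "hc_vs_pd", subset = function(df) rep(TRUE, nrow(df)),
           label = function(df) as.integer(!df$is_control)),
      list(name = "score1_vs_23", subset = function(df) df$score >= 1,
           label = function(df) as.integer(df$score >= 2)),
      list(name = "score2_vs_3", subset = function(df) df$score %in% c(2, 3),
           label = function(df) as.integer(df$score == 3))),
    tk_stop(sprintf("unknown scheme: %s", scheme), "tk_usage_error"))
}

encode_sex <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex))
  as.numeric(toupper(as.character(sex)) %in% c("M", "MALE", "1"))
}

# Raw feature rows -> standardized candidate matrix via the fitted scaler.
scale_candidates <- function(rows, scaler) {
  missing <- setdiff(scaler$features, c(names(rows)))
  tk_assert(length(missing) == 0,
            sprintf("missing feature column(s): %s",
                    paste(missing, collapse = ", ")), "tk_schema_error")
  rows <- as.data.frame(rows)
  rows$sex <- encode_sex(rows$sex)
  X <- as.matrix(rows[, scaler$features, drop = FALSE])
  Xs <- scale(X, center = scaler$center, scale = scaler$scale)
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  Xs
}

#' Fit a severity-prediction scheme
#'
#' Performs a stratified 70/30 split (by score), fits the z-score scaler on
#' training rows only, then per constituent model: subsets/relabels the
#' training rows for the scheme, balances classes with
#' [balance_classes()] (training rows only), selects features with
#' [rfe_select()], and fits the final L2 logistic model. The held-out test
#' rows are evaluated with [evaluate()].
#'
#' @param table Feature table with [FEATURE_NAMES], `age`, `sex`, `score`
#'   (0-3), and — for the tiered scheme — `is_control`.
#' @param scheme `"multiclass"`, `"ordinal"`, or `"tiered"`.
#' @param protocol A [split_protocol()].
#' @param epsilon RFE stopping tolerance (default 0.005).
#' @param lambda Ridge penalty (default 1).
#' @return A `severity_model_bundle`: scaler, per-model selected features and
#'   coefficients, split indices, and a `metrics` report.
#' @export
fit_scheme <- function(table, scheme = c("tiered", "ordinal", "multiclass"),
                       protocol = split_protocol(), epsilon = 0.005,
                       lambda = 1) {
  scheme <- match.arg(scheme)
  tk_assert("score" %in% names(table), "table must have a score column",
            "tk_usage_error")
  if (scheme == "tiered") {
    tk_assert("is_control" %in% names(table),
              "tiered scheme requires an is_control column", "tk_usage_error")
  }
  sp <- stratified_split(table$score, protocol$test_fraction, protocol$seed)
  train <- table[sp$train, , drop = FALSE]
  seeds <- derive_seeds(protocol$seed, 8L)
  # scaler from training rows only
  tr_enc <- train
  tr_enc$sex <- encode_sex(tr_enc$sex)
  Xtr_raw <- as.matrix(tr_enc[, MODEL_CANDIDATES, drop = FALSE])
  scaler <- list(features = MODEL_CANDIDATES,
                 center = colMeans(Xtr_raw),
                 scale = apply(Xtr_raw, 2L, stats::sd))
  scaler$scale[scaler$scale == 0] <- 1
  models <- list()
  defs <- scheme_models(scheme)
  for (i in seq_along(defs)) {
    def <- defs[[i]]
    sub <- train[def$subset(train), , drop = FALSE]
    y <- def$label(sub)
    if (length(unique(y)) < 2L) {
      tk_stop(sprintf("model '%s': training subset has a single class",
                      def$name), "tk_tier_degeneracy_error")
    }
    Xs <- scale_candidates(sub, scaler)
    df_bal <- as.data.frame(Xs)
    df_bal$..y.. <- y
    bal <- balance_classes(df_bal, label_col = "..y..",
                           feature_cols = scaler$features,
                           seed = seeds[i])
    Xb <- as.matrix(bal[, scaler$features, drop = FALSE])
    yb <- bal$..y..
    sel <- rfe_select(Xb, yb, n_folds = protocol$n_folds,
                      seed = seeds[i + 4L], epsilon = epsilon,
                      lambda = lambda)
    fit <- fit_logit_model(Xb[, sel, drop = FALSE], yb, lambda)
    models[[def$name]] <- list(name = def$name, features = sel, fit = fit)
  }
  bundle <- structure(list(scheme = scheme, scaler = scaler, models = models,
                           protocol = protocol, lambda = lambda,
                           train_idx = sp$train, test_idx = sp$test),
                      class = "severity_model_bundle")
  bundle$metrics <- evaluate(bundle, table[sp$test, , drop = FALSE])
  bundle
}

#' @export
print.severity_model_bundle <- function(x, ...) {
  cat(sprintf("<severity_model_bundle> scheme = %s\n", x$scheme))
  for (m in x$models) {
    cat(sprintf("  %s: %d features [%s]\n", m$name, length(m$features),
                paste(m$features, collapse = ", ")))
  }
  if (!is.null(x$metrics)) {
    cat(sprintf("  test macro accuracy: %.3f\n",
                x$metrics$overall$macro_accuracy))
  }
  invisible(x)
}

model_probs <- function(bundle, rows, name) {
  m <- bundle$models[[name]]
  X <- scale_candidates(rows, bundle$scaler)
  predict_logit(m$fit, X[, m$features, drop = FALSE])
}

# Class-probability matrix for the multiclass model (handles the 2-class
# degenerate case where the fit collapses to a single binary model).
multiclass_probs <- function(bundle, rows) {
  p <- model_probs(bundle, rows, "multiclass")
  fit <- bundle$models$multiclass$fit
  if (fit$type == "binary") {
    p <- cbind(1 - p, p)
    colnames(p) <- as.character(fit$levels)
  }
  p
}

#' Tiered and ordinal routing rules
#'
#' `route_tiered`: tier-1 probability <= 0.5 stops at score 0, else tier-2
#' <= 0.5 stops at 1, else tier-3 assigns 2 (<= 0.5) or 3. `route_ordinal`:
#' score = number of cumulative dichotomies voting above 0.5 (sum rule).
#' Pure functions of the probabilities; exported so routing can be audited
#' independently of any fitted model.
#'
#' @param p1,p2,p3 Probability vectors from the three constituent models.
#' @return Integer score vector (0-3).
#' @export
route_tiered <- function(p1, p2, p3) {
  ifelse(p1 <= 0.5, 0L, ifelse(p2 <= 0.5, 1L, ifelse(p3 <= 0.5, 2L, 3L)))
}

#' @rdname route_tiered
#' @export
route_ordinal <- function(p1, p2, p3) {
  as.integer((p1 > 0.5) + (p2 > 0.5) + (p3 > 0.5))
}

#' Predict severity scores with the tiered cascade
#'
#' Tier 1 (control vs PD) probability <= 0.5 stops at score 0; otherwise
#' tier 2 (score 1 vs 2-3) <= 0.5 stops at score 1; otherwise tier 3
#' (score 2 vs 3) assigns 2 (<= 0.5) or 3. Ties at exactly 0.5 go to the
#' lower-severity branch.
#'
#' @param bundle A tiered `severity_model_bundle`.
#' @param rows Feature rows (data frame with the candidate columns).
#' @return Data frame with `score` and the three tier probabilities.
#' @export
predict_tiered <- function(bundle, rows) {
  tk_assert(bundle$scheme == "tiered", "bundle scheme is not 'tiered'",
            "tk_usage_error")
  p1 <- model_probs(bundle, rows, "hc_vs_pd")
  p2 <- model_probs(bundle, rows, "score1_vs_23")
  p3 <- model_probs(bundle, rows, "score2_vs_3")
  data.frame(score = route_tiered(p1, p2, p3),
             p_tier1 = p1, p_tier2 = p2, p_tier3 = p3)
}

#' Predict severity scores from the ordinal cumulative dichotomies
#'
#' Score = number of the three cumulative models (0|123, 01|23, 012|3)
#' voting above threshold — the standard cumulative-dichotomy sum rule.
#' Non-monotone vote patterns (e.g. 1,0,1) are counted in the
#' `n_non_monotone` attribute rather than silently resolved.
#'
#' @param bundle An ordinal `severity_model_bundle`.
#' @param rows Feature rows.
#' @return Data frame with `score` and the three model probabilities;
#'   attribute `n_non_monotone`.
#' @export
predict_ordinal <- function(bundle, rows) {
  tk_assert(bundle$scheme == "ordinal", "bundle scheme is not 'ordinal'",
            "tk_usage_error")
  p1 <- model_probs(bundle, rows, "score0_vs_123")
  p2 <- model_probs(bundle, rows, "score01_vs_23")
  p3 <- model_probs(bundle, rows, "score012_vs_3")
  votes <- cbind(p1 > 0.5, p2 > 0.5, p3 > 0.5)
  out <- data.frame(score = route_ordinal(p1, p2, p3),
                    p_model1 = p1, p_model2 = p2, p_model3 = p3)
  non_mono <- apply(votes, 1L, function(v) any(diff(as.integer(v)) > 0))
  attr(out, "n_non_monotone") <- sum(non_mono)
  out
}

#' Predict severity scores with any fitted scheme
#'
#' @param bundle A `severity_model_bundle`.
#' @param rows Feature rows.
#' @return Data frame with at least a `score` column.
#' @export
predict_scheme <- function(bundle, rows) {
  switch(bundle$scheme,
    tiered = predict_tiered(bundle, rows),
    ordinal = predict_ordinal(bundle, rows),
    multiclass = {
      p <- multiclass_probs(bundle, rows)
      lev <- bundle$models$multiclass$fit$levels
      data.frame(score = as.integer(lev[max.col(p, ties.method = "first")]))
    })
}

#' Evaluate a fitted bundle on held-out rows
#'
#' Reports, per constituent model, PR-AUC (average precision), f1, per-class
#' accuracy (class-wise recall), confusion matrix and the selected features,
#' plus overall predicted-score metrics for the scheme. Tier 2/3 of the
#' cascade are evaluated on the test rows belonging to their own dichotomy
#' (true score >= 1 and true score in 2-3 respectively).
#'
#' @param bundle A `severity_model_bundle`.
#' @param test_rows Feature rows disjoint from training.
#' @return A `metrics_report` list: `per_model`, `overall`.
#' @export
evaluate <- function(bundle, test_rows) {
  tk_assert(length(unique(test_rows$score)) >= 2,
            "undefined metric: test set contains a single class",
            "tk_undefined_metric_error")
  per_model <- list()
  if (bundle$scheme == "multiclass") {
    p <- multiclass_probs(bundle, test_rows)
    lev <- bundle$models$multiclass$fit$levels
    pred <- as.integer(lev[max.col(p, ties.method = "first")])
    truth <- test_rows$score
    # prevalence-weighted mean of one-vs-rest PR-AUCs
    prev <- table(factor(truth, levels = lev)) / length(truth)
    aucs <- vapply(seq_along(lev), function(i) {
      if (prev[i] == 0 || prev[i] == 1) return(NA_real_)
      pr_auc(p[, i], truth == lev[i])
    }, numeric(1))
    per_model$multiclass <- list(
      pr_auc = sum(prev[!is.na(aucs)] * aucs[!is.na(aucs)]) /
        sum(prev[!is.na(aucs)]),
      f1 = macro_f1(truth, pred, levels = lev),
      per_class_accuracy = per_class_accuracy(truth, pred, levels = lev),
      confusion = confusion_matrix(truth, pred, levels = lev),
      features = bundle$models$multiclass$features)
  } else {
    defs <- scheme_models(bundle$scheme)
    for (def in defs) {
      sub <- test_rows[def$subset(test_rows), , drop = FALSE]
      y <- def$label(sub)
      m <- bundle$models[[def$name]]
      if (length(unique(y)) < 2L) {
        per_model[[def$name]] <- list(pr_auc = NA_real_, f1 = NA_real_,
                                      per_class_accuracy = NA,
                                      confusion = NULL,
                                      features = m$features,
                                      note = "single-class test subset")
        next
      }
      p <- model_probs(bundle, sub, def$name)
      pred <- as.integer(p > 0.5)
      per_model[[def$name]] <- list(
        pr_auc = pr_auc(p, y == 1L),
        f1 = binary_prf(y, pred, positive = 1L)[["f1"]],
        per_class_accuracy = per_class_accuracy(y, pred, levels = c(0L, 1L)),
        confusion = confusion_matrix(y, pred, levels = c(0L, 1L)),
        features = m$features)
    }
  }
  pred_score <- predict_scheme(bundle, test_rows)$score
  lev <- sort(unique(test_rows$score))
  pca <- per_class_accuracy(test_rows$score, pred_score, levels = lev)
  overall <- list(
    accuracy = mean(pred_score == test_rows$score),
    macro_accuracy = mean(pca, na.rm = TRUE),
    per_class_accuracy = pca,
    f1 = macro_f1(test_rows$score, pred_score, levels = lev),
    confusion = confusion_matrix(test_rows$score, pred_score, levels = lev))
  structure(list(scheme = bundle$scheme, per_model = per_model,
                 overall = overall), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> scheme = %s\n", x$scheme))
  for (nm in names(x$per_model)) {
    m <- x$per_model[[nm]]
    cat(sprintf("  %s: PR-AUC %.3f, f1 %.3f | features: %s\n",
                nm, m$pr_auc, m$f1, paste(m$features, collapse = ", ")))
  }
  cat(sprintf("  overall: accuracy %.3f, macro accuracy %.3f, macro f1 %.3f\n",
              x$overall$accuracy, x$overall$macro_accuracy, x$overall$f1))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report A `metrics_report` (e.g. `bundle$metrics`).
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  ser <- list(scheme = report$scheme,
              per_model = lapply(report$per_model, function(m) {
                m$confusion <- if (!is.null(m$confusion))
                  as.data.frame.matrix(m$confusion) else NULL
                m
              }),
              overall = within(report$overall, {
                confusion <- as.data.frame.matrix(confusion)
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

# --- bundle serialization ---------------------------------------------------

#' Serialize / restore a fitted bundle as JSON
#'
#' The JSON carries scaler parameters, per-model selected features and
#' coefficients, and metadata; restoring gives identical predictions.
#'
#' @param bundle A `severity_model_bundle`.
#' @param path JSON path.
#' @return `path` (write) / the bundle (read).
#' @export
write_bundle <- function(bundle, path) {
  ser <- list(
    package = "tapkin", scheme = bundle$scheme, lambda = bundle$lambda,
    scaler = bundle$scaler,
    protocol = unclass(bundle$protocol),
    models = lapply(bundle$models, function(m) {
      list(name = m$name, features = m$features, type = m$fit$type,
           levels = m$fit$levels,
           beta = if (m$fit$type == "binary") as.list(m$fit$beta) else
             lapply(m$fit$betas, as.list))
    }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  ser <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  tk_assert(identical(ser$package, "tapkin"), "not a tapkin bundle",
            "tk_schema_error")
  models <- list()
  for (nm in names(ser$models)) {
    m <- ser$models[[nm]]
    fit <- if (m$type == "binary") {
      structure(list(type = "binary", levels = m$levels,
                     beta = unlist(m$beta)), class = "tk_logit")
    } else {
      structure(list(type = "ovr", levels = m$levels,
                     betas = lapply(m$beta, unlist)), class = "tk_logit")
    }
    models[[nm]] <- list(name = m$name, features = m$features, fit = fit)
  }
  structure(list(scheme = ser$scheme, lambda = ser$lambda,
                 scaler = list(features = ser$scaler$features,
                               center = unlist(ser$scaler$center),
                               scale = unlist(ser$scaler$scale)),
                 protocol = do.call(split_protocol, as.list(ser$protocol)),
                 models = models),
            class = "severity_model_bundle")
}
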