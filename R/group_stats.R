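# Per-feature group comparison across severity scores: normality screening,
# classical or Welch one-way ANOVA, and Tukey HSD post-hoc with a Bonferroni
# correction across the number of features tested.

#' Kolmogorov-Smirnov normality screen per group
#'
#' Each group's values are standardized and compared against the standard
#' normal with a one-sample KS test; a group is flagged non-normal when
#' p < `alpha`. Note that testing standardized values against N(0, 1) with
#' estimated parameters is anti-conservative; `lilliefors = TRUE` calibrates
#' the p-value against a seeded Monte Carlo null with estimated parameters.
#' Zero-variance groups are non-testable and treated as non-normal.
#'
#' @param groups Named list of numeric vectors (each n >= 3).
#' @param alpha Screening level (default 0.05).
#' @param lilliefors Use the Monte Carlo Lilliefors correction.
#' @param n_sim Monte Carlo replicates for the Lilliefors null (default 1000).
#' @param seed Seed for the Monte Carlo null.
#' @return Named logical vector, `TRUE` = consistent with normality.
#' @export
normality_screen <- function(groups, alpha = 0.05, lilliefors = FALSE,
                             n_sim = 1000L, seed = 1L) {
  tk_assert(all(vapply(groups, length, integer(1)) >= 3L),
            "each group needs n >= 3", "tk_usage_error")
  vapply(groups, function(x) {
    if (stats::sd(x) == 0) return(FALSE)  # non-testable -> non-normal
    z <- (x - mean(x)) / stats::sd(x)
    d_obs <- suppressWarnings(stats::ks.test(z, "pnorm"))
    if (!lilliefors) return(d_obs$p.value >= alpha)
    null_d <- with_seed(seed, vapply(seq_len(n_sim), function(i) {
      s <- stats::rnorm(length(x))
      zz <- (s - mean(s)) / stats::sd(s)
      suppressWarnings(stats::ks.test(zz, "pnorm"))$statistic
    }, numeric(1)))
    mean(null_d >= d_obs$statistic) >= alpha
  }, logical(1))
}

#' One-way omnibus test: classical or Welch ANOVA
#'
#' Runs Welch's heteroscedasticity-robust ANOVA when any group fails the
#' normality screen (or when forced), classical one-way ANOVA otherwise.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param force Optional `"anova"` or `"welch"` to bypass the screen.
#' @param alpha Normality-screen level.
#' @return List with `F`, `p`, `test_used`, `df1`, `df2`, `normal` (per-group
#'   screen result, `NULL` when forced).
#' @export
omnibus_test <- function(groups, force = NULL, alpha = 0.05) {
  tk_assert(length(groups) >= 2L, "need at least 2 groups", "tk_usage_error")
  tk_assert(all(vapply(groups, length, integer(1)) >= 2L),
            "each group needs n >= 2", "tk_usage_error")
  normal <- NULL
  if (is.null(force)) {
    normal <- normality_screen(groups, alpha = alpha)
    test <- if (all(normal)) "anova" else "welch"
  } else {
    test <- match.arg(force, c("anova", "welch"))
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  res <- stats::oneway.test(x ~ g, var.equal = (test == "anova"))
  list(F = unname(res$statistic), p = unname(res$p.value), test_used = test,
       df1 = unname(res$parameter[1]), df2 = unname(res$parameter[2]),
       normal = normal)
}

p_stars <- function(p) {
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 1e-2, "**",
                       ifelse(p <= 5e-2, "*", ""))))
}

# Games-Howell pairwise comparison (Welch-type post-hoc), offered behind a
# flag; Tukey is the default to match the published analysis.
games_howell_pair <- function(xi, xj, k) {
  ni <- length(xi); nj <- length(xj)
  vi <- stats::var(xi) / ni; vj <- stats::var(xj) / nj
  se <- sqrt(vi + vj)
  df <- (vi + vj)^2 / (vi^2 / (ni - 1) + vj^2 / (nj - 1))
  q <- abs(mean(xi) - mean(xj)) / (se / sqrt(2))
  list(diff = mean(xj) - mean(xi),
       p = stats::ptukey(q, k, df, lower.tail = FALSE))
}

#' Pairwise post-hoc comparisons with Bonferroni correction across features
#'
#' All group pairs are compared with Tukey's Honest Significant Difference
#' (studentized-range distribution); each Tukey p-value is then multiplied by
#' `n_features_for_bonferroni` (capped at 1) to correct for testing many
#' features, and binned into significance stars
#' (`*` 0.01 < p <= 0.05, `**` 0.001 < p <= 0.01, `***` 1e-4 < p <= 1e-3,
#' `****` p <= 1e-4).
#'
#' @param groups Named list of numeric vectors.
#' @param n_features_for_bonferroni Number of features tested in the family
#'   (default 1 = no across-feature correction).
#' @param method `"tukey"` (default) or `"games-howell"`.
#' @return Data frame: `group1`, `group2`, `diff`, `p_raw`, `p_corrected`,
#'   `stars`; pairs with combined n < 3 are skipped (`skipped` attribute).
#' @export
posthoc_pairwise <- function(groups, n_features_for_bonferroni = 1L,
                             method = c("tukey", "games-howell")) {
  method <- match.arg(method)
  nms <- names(groups)
  if (is.null(nms)) nms <- as.character(seq_along(groups))
  k <- length(groups)
  rows <- list()
  skipped <- character(0)
  if (method == "tukey") {
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(nms, vapply(groups, length, integer(1))), levels = nms)
    tuk <- stats::TukeyHSD(stats::aov(x ~ g))$g
  }
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ni <- length(groups[[i]]); nj <- length(groups[[j]])
    if (ni + nj < 3L || ni < 2L || nj < 2L) {
      skipped <- c(skipped, sprintf("%s-%s: combined n too small",
                                    nms[j], nms[i]))
      next
    }
    if (method == "tukey") {
      key <- sprintf("%s-%s", nms[j], nms[i])
      d <- tuk[key, "diff"]
      p <- tuk[key, "p adj"]
    } else {
      gh <- games_howell_pair(groups[[i]], groups[[j]], k)
      d <- gh$diff
      p <- gh$p
    }
    pc <- min(1, p * n_features_for_bonferroni)
    rows[[length(rows) + 1L]] <-
      data.frame(group1 = nms[i], group2 = nms[j], diff = unname(d),
                 p_raw = unname(p), p_corrected = pc, stars = p_stars(pc))
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(group1 = character(0), group2 = character(0),
               diff = numeric(0), p_raw = numeric(0),
               p_corrected = numeric(0), stars = character(0))
  attr(out, "skipped") <- skipped
  out
}

#' Group comparison across all kinematic features
#'
#' For each feature: per-group normality screen, classical or Welch omnibus
#' ANOVA, and — when the omnibus p < `alpha` — Tukey HSD pairwise
#' comparisons Bonferroni-corrected by the number of features tested.
#'
#' @param table Feature table with a group column (default `score`).
#' @param group_col Grouping column name.
#' @param features Feature columns to test (default: the canonical 13
#'   present in the table).
#' @param alpha Significance level (default 0.05).
#' @param posthoc_method Passed to [posthoc_pairwise()].
#' @return A `group_comparison_report`: `per_feature` data frame (feature,
#'   group means/SDs, test used, F, p, significant), `pairwise` data frame,
#'   `alpha`, `n_features`.
#' @export
compare_all_features <- function(table, group_col = "score",
                                 features = intersect(FEATURE_NAMES,
                                                      names(table)),
                                 alpha = 0.05,
                                 posthoc_method = "tukey") {
  tk_assert(group_col %in% names(table), "group column not found",
            "tk_usage_error")
  g <- table[[group_col]]
  lev <- sort(unique(g))
  tk_assert(length(lev) >= 2L, "need at least 2 groups", "tk_usage_error")
  tk_assert(length(features) >= 1L, "no features to test", "tk_usage_error")
  n_feat <- length(features)
  per <- list()
  pw <- list()
  for (f in features) {
    groups <- lapply(stats::setNames(lev, as.character(lev)),
                     function(l) table[[f]][g == l])
    om <- omnibus_test(groups, alpha = alpha)
    mean_sd <- vapply(groups, function(x)
      sprintf("%.2f±%.2f", mean(x), stats::sd(x)), character(1))
    row <- data.frame(feature = f, test_used = om$test_used,
                      F = om$F, p = om$p, significant = om$p < alpha)
    for (l in names(mean_sd)) row[[paste0("group_", l)]] <- mean_sd[[l]]
    per[[f]] <- row
    if (om$p < alpha) {
      tab <- posthoc_pairwise(groups, n_features_for_bonferroni = n_feat,
                              method = posthoc_method)
      if (nrow(tab) > 0) {
        tab <- cbind(feature = f, tab)
        pw[[f]] <- tab
      }
    }
  }
  structure(list(
    per_feature = do.call(rbind, c(per, make.row.names = FALSE)),
    pairwise = if (length(pw) > 0)
      do.call(rbind, c(pw, make.row.names = FALSE)) else NULL,
    alpha = alpha, n_features = n_feat),
    class = "group_comparison_report")
}

#' @export
print.group_comparison_report <- function(x, ...) {
  cat(sprintf("<group_comparison_report> %d features, alpha = %g\n",
              x$n_features, x$alpha))
  print(x$per_feature[, c("feature", "test_used", "F", "p", "significant")],
        row.names = FALSE)
  invisible(x)
}

#' Write a group-comparison report to JSON (and optionally CSVs)
#'
#' @param report A [compare_all_features()] result.
#' @param path JSON output path.
#' @param csv_prefix Optional path prefix; writes `<prefix>_features.csv` and
#'   `<prefix>_pairwise.csv`.
#' @return `path`, invisibly.
#' @export
write_group_report <- function(report, path, csv_prefix = NULL) {
  jsonlite::write_json(list(alpha = report$alpha,
                            n_features = report$n_features,
                            per_feature = report$per_feature,
                            pairwise = report$pairwise),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(csv_prefix)) {
    utils::write.csv(report$per_feature, paste0(csv_prefix, "_features.csv"),
                     row.names = FALSE)
    if (!is.null(report$pairwise)) {
      utils::write.csv(report$pairwise, paste0(csv_prefix, "_pairwise.csv"),
                       row.names = FALSE)
    }
  }
  invisible(path)
}
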