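# Normality screen, omnibus ANOVA/Welch, Tukey post-hoc, full report.

test_that("KS screen separates normal from exponential samples", {
  norm_flags <- vapply(1:20, function(s) {
    set.seed(s)
    normality_screen(list(g = rnorm(500)))[["g"]]
  }, logical(1))
  expect_gte(mean(norm_flags), 0.9)
  exp_flags <- vapply(1:20, function(s) {
    set.seed(s + 1000)
    normality_screen(list(g = rexp(500)))[["g"]]
  }, logical(1))
  expect_lte(mean(exp_flags), 0.1)
  # zero-variance group is non-testable, treated as non-normal
  expect_false(normality_screen(list(g = rep(1, 10)))[["g"]])
  expect_error(normality_screen(list(g = c(1, 2))), class = "tk_usage_error")
})

test_that("two-group classical ANOVA F equals the pooled t statistic squared", {
  set.seed(12)
  g <- list(a = rnorm(20, 0), b = rnorm(25, 0.7))
  om <- omnibus_test(g, force = "anova")
  tt <- t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(om$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(om$p, tt$p.value, tolerance = 1e-10)
})

test_that("identical groups give F = 0, p = 1", {
  g <- list(a = 1:10, b = 1:10, c = 1:10)
  om <- omnibus_test(g)
  expect_equal(om$F, 0, tolerance = 1e-12)
  expect_equal(om$p, 1, tolerance = 1e-12)
  expect_error(omnibus_test(list(a = 1:5)), class = "tk_usage_error")
})

test_that("Welch ANOVA matches an independent implementation of the formula", {
  welch_brute <- function(groups) {
    ni <- sapply(groups, length)
    mi <- sapply(groups, mean)
    vi <- sapply(groups, var)
    wi <- ni / vi
    mw <- sum(wi * mi) / sum(wi)
    k <- length(groups)
    A <- sum(wi * (mi - mw)^2) / (k - 1)
    B <- 1 + 2 * (k - 2) / (k^2 - 1) * sum((1 - wi / sum(wi))^2 / (ni - 1))
    df2 <- (k^2 - 1) / (3 * sum((1 - wi / sum(wi))^2 / (ni - 1)))
    c(F = A / B, p = pf(A / B, k - 1, df2, lower.tail = FALSE))
  }
  g <- list(a = c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6,
                  23.1, 19.6),
            b = c(24.5, 23.4, 34.6, 19.9, 26.1, 27.3, 19.6, 23.3, 16.5, 23.2),
            c = c(26.4, 24.3, 28.6, 20.2, 27.1, 27.9, 33.5, 26.4, 28.5, 29.4))
  om <- omnibus_test(g, force = "welch")
  bo <- welch_brute(g)
  expect_equal(om$F, unname(bo["F"]), tolerance = 1e-10)
  expect_equal(om$p, unname(bo["p"]), tolerance = 1e-10)
})

test_that("Welch reduces to classical ANOVA under homoscedastic equal n", {
  # shared draws shifted per group: sample variances exactly equal, so the
  # Welch/classical ratio is exactly 1/B with B = 1 + O(1/n)
  for (s in 1:10) {
    set.seed(s)
    z <- rnorm(50)
    g <- lapply(1:3, function(i) z + 0.3 * i)
    fa <- omnibus_test(g, force = "anova")$F
    fw <- omnibus_test(g, force = "welch")$F
    expect_lt(abs(fw / fa - 1), 0.01)
  }
})

test_that("Tukey post-hoc: nulls stay null, large shifts hit ****", {
  g <- list(a = 1:10, b = 1:10, c = 1:10)
  tab <- posthoc_pairwise(g)
  expect_true(all(tab$stars == ""))
  for (s in 1:20) {
    set.seed(s)
    g2 <- list(a = rnorm(30, 0, 1), b = rnorm(30, 5, 1))
    tab2 <- posthoc_pairwise(g2)
    expect_identical(tab2$stars, "****")
  }
  # Bonferroni correction is monotone in the number of features
  set.seed(30)
  g3 <- list(a = rnorm(15), b = rnorm(15, 0.8), c = rnorm(15, 1.2))
  p1 <- posthoc_pairwise(g3, n_features_for_bonferroni = 1)$p_corrected
  p5 <- posthoc_pairwise(g3, n_features_for_bonferroni = 5)$p_corrected
  p13 <- posthoc_pairwise(g3, n_features_for_bonferroni = 13)$p_corrected
  expect_true(all(p5 >= p1))
  expect_true(all(p13 >= p5))
  expect_true(all(p13 <= 1))
  # star bins
  expect_identical(tapkin:::p_stars(c(0.04, 0.009, 5e-4, 5e-5, 0.2)),
                   c("*", "**", "***", "****", ""))
})

test_that("Games-Howell variant agrees with Tukey when variances are equal", {
  set.seed(21)
  # heteroscedastic data: same mean differences, p-values may differ
  g <- list(a = rnorm(25, 0, 1), b = rnorm(25, 1.5, 2), c = rnorm(25, 3, 0.5))
  tuk <- posthoc_pairwise(g, method = "tukey")
  gh <- posthoc_pairwise(g, method = "games-howell")
  expect_equal(gh$diff, tuk$diff, tolerance = 1e-9)
  # homoscedastic equal-n data: the two post-hocs approximately coincide
  z <- rnorm(40)
  g2 <- list(a = z, b = z + 0.4, c = z + 0.8)
  tuk2 <- posthoc_pairwise(g2, method = "tukey")
  gh2 <- posthoc_pairwise(g2, method = "games-howell")
  expect_equal(gh2$p_raw, tuk2$p_raw, tolerance = 0.02)
})

test_that("feature-wise report flags the constructed difference only", {
  # presets differing only in amplitude: amplitude significant, CVs not
  presets <- severity_presets()[c("0", "1")]
  p0 <- presets[["0"]]$params
  for (k in names(presets)) {
    presets[[k]]$params <- p0
    presets[[k]]$params$mean_peak_to_valley <- c(`0` = 40, `1` = 22)[[k]]
    presets[[k]]$between_sd <- lapply(presets[[k]]$between_sd, function(x) 0)
    presets[[k]]$score <- as.integer(k)
  }
  coh <- simulate_cohort(15L, presets, feature_noise_scale = 0,
                         seed = 17L, scores = 0:1)
  rep <- compare_all_features(coh)
  pf <- rep$per_feature
  expect_true(pf$significant[pf$feature == "mean_amplitude"])
  expect_false(pf$significant[pf$feature == "cv_amplitude"])
  expect_false(pf$significant[pf$feature == "cv_cycle_duration"])
  expect_true("mean_amplitude" %in% rep$pairwise$feature)
  # single-group table -> usage error
  expect_error(compare_all_features(coh[coh$score == 0, ]),
               class = "tk_usage_error")
})

test_that("shuffled labels reject at roughly the nominal rate", {
  coh <- simulate_cohort(15L, feature_noise_scale = 0.5, seed = 23L)
  set.seed(31)
  fracs <- replicate(60, {
    sh <- coh
    sh$score <- sample(sh$score)
    rep <- compare_all_features(sh)
    mean(rep$per_feature$significant)
  })
  expect_lt(abs(mean(fracs) - 0.05), 0.04)
})
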