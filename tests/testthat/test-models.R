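# Severity models: RFE, schemes, routing, serialization, leakage.

test_that("RFE eliminates pure-noise features on separable data", {
  # three informative features jointly carry the class signal (each one is
  # needed), five are pure noise
  # epsilon is set to the scale of the 5-fold f1 estimation noise (~0.03);
  # far below it, selection reduces to the noisy path argmax (winner's
  # curse) and the property is not well-posed
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 300
    X <- matrix(rnorm(n * 8), n, 8)
    colnames(X) <- c(paste0("info", 1:3), paste0("noise", 1:5))
    eta <- 3.5 * (X[, 1] + X[, 2] + X[, 3]) / sqrt(3)
    y <- rbinom(n, 1, plogis(eta))
    sel <- rfe_select(scale(X), y, seed = s, epsilon = 0.03)
    if (all(paste0("info", 1:3) %in% sel) &&
        !any(paste0("noise", 1:5) %in% sel)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 18L)  # >= 90% of 20 seeds
})

test_that("RFE limit behavior: epsilon = Inf keeps one feature; copies collapse", {
  set.seed(10)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- cbind(a = rnorm(n, y * 2), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  X <- scale(X)
  sel <- rfe_select(X, y, seed = 1L, epsilon = Inf)
  expect_length(sel, 1L)
  # identical copies: exactly one survives, tie-broken by fixed column order
  z <- scale(rnorm(n, y * 2))[, 1]
  Xc <- cbind(c1 = z, c2 = z, c3 = z)
  sel2 <- rfe_select(Xc, y, seed = 1L)
  expect_identical(sel2, "c1")
})

test_that("tiered and ordinal routing match exhaustive enumeration", {
  grid <- expand.grid(p1 = c(0.1, 0.3, 0.5, 0.7, 0.9),
                      p2 = c(0.1, 0.5, 0.9), p3 = c(0.2, 0.5, 0.8))
  # independent decision-tree oracle, written as explicit branches
  oracle_tier <- apply(grid, 1, function(p) {
    if (p["p1"] <= 0.5) return(0L)
    if (p["p2"] <= 0.5) return(1L)
    if (p["p3"] <= 0.5) return(2L)
    3L
  })
  expect_identical(route_tiered(grid$p1, grid$p2, grid$p3), oracle_tier)
  oracle_ord <- apply(grid, 1, function(p) {
    sum(c(p["p1"] > 0.5, p["p2"] > 0.5, p["p3"] > 0.5))
  })
  expect_identical(route_ordinal(grid$p1, grid$p2, grid$p3),
                   as.integer(oracle_ord))
  # spot rules from the cascade definition
  expect_identical(route_tiered(0.2, 0.9, 0.9), 0L)
  expect_identical(route_tiered(0.9, 0.9, 0.2), 2L)
  expect_identical(route_ordinal(0.9, 0.1, 0.9), 2L)  # non-monotone sum rule
  expect_identical(route_ordinal(0.1, 0.1, 0.1), 0L)
})

test_that("all three schemes fit, predict and report on a separable table", {
  tab <- make_toy_model_table(n_per_class = 30, sep = 4, seed = 2)
  for (scheme in c("tiered", "ordinal", "multiclass")) {
    b <- fit_scheme(tab, scheme, split_protocol(seed = 3L))
    expect_s3_class(b, "severity_model_bundle")
    expect_gte(b$metrics$overall$macro_accuracy, 0.8)
    pred <- predict_scheme(b, tab)
    expect_true(all(pred$score %in% 0:3))
  }
})

test_that("ordinal predictions report non-monotone vote patterns", {
  tab <- make_toy_model_table(n_per_class = 20, sep = 3, seed = 5)
  b <- fit_scheme(tab, "ordinal", split_protocol(seed = 5L))
  pred <- predict_ordinal(b, tab)
  expect_false(is.null(attr(pred, "n_non_monotone")))
  expect_identical(pred$score,
                   route_ordinal(pred$p_model1, pred$p_model2, pred$p_model3))
})

test_that("multiclass PR-AUC is 1 on two perfectly separated classes", {
  set.seed(8)
  n <- 40
  tab <- make_toy_model_table(n_per_class = 20, seed = 8)
  tab <- tab[tab$score %in% c(0, 1), ]
  tab$mean_amplitude <- ifelse(tab$score == 0, 10, -10) + rnorm(40, 0, 0.1)
  b <- fit_scheme(tab, "multiclass", split_protocol(seed = 8L))
  expect_equal(b$metrics$per_model$multiclass$pr_auc, 1)
  expect_equal(unname(b$metrics$overall$per_class_accuracy), c(1, 1))
})

test_that("bundle JSON round-trip preserves predictions exactly", {
  tab <- make_toy_model_table(n_per_class = 20, seed = 6)
  for (scheme in c("tiered", "ordinal")) {
    b <- fit_scheme(tab, scheme, split_protocol(seed = 6L))
    f <- tmp_path(".json")
    write_bundle(b, f)
    b2 <- read_bundle(f)
    expect_equal(predict_scheme(b2, tab)$score, predict_scheme(b, tab)$score)
    p1 <- predict_scheme(b, tab)
    p2 <- predict_scheme(b2, tab)
    expect_equal(p2, p1, tolerance = 1e-12, ignore_attr = TRUE)
    unlink(f)
  }
})

test_that("fitting is reproducible and leakage-free", {
  tab <- make_toy_model_table(n_per_class = 25, seed = 9)
  b1 <- fit_scheme(tab, "tiered", split_protocol(seed = 4L))
  b2 <- fit_scheme(tab, "tiered", split_protocol(seed = 4L))
  expect_identical(b1$scaler, b2$scaler)
  expect_identical(lapply(b1$models, `[[`, "features"),
                   lapply(b2$models, `[[`, "features"))
  expect_identical(lapply(b1$models, function(m) m$fit$beta),
                   lapply(b2$models, function(m) m$fit$beta))
  # perturb held-out rows only: fitted artifacts must not move
  tab3 <- tab
  tab3[b1$test_idx, FEATURE_NAMES] <- tab3[b1$test_idx, FEATURE_NAMES] * 3 + 7
  b3 <- fit_scheme(tab3, "tiered", split_protocol(seed = 4L))
  expect_identical(b1$scaler, b3$scaler)
  expect_identical(lapply(b1$models, `[[`, "features"),
                   lapply(b3$models, `[[`, "features"))
  expect_identical(lapply(b1$models, function(m) m$fit$beta),
                   lapply(b3$models, function(m) m$fit$beta))
})

test_that("tiered predictions are monotone in preset severity (sweep)", {
  train <- simulate_cohort(40L, feature_noise_scale = 0.25, seed = 19L)
  b <- fit_scheme(train, "tiered", split_protocol(seed = 19L))
  # 5 subjects per class: enough for the per-class median to be a stable
  # statistic (3/class makes it flip on single predictions)
  for (r in 1:20) {
    coh <- simulate_cohort(5L, feature_noise_scale = 0.25, seed = 100L + r)
    med <- tapply(predict_tiered(b, coh)$score, coh$score, median)
    expect_true(all(diff(med) >= 0), label = sprintf("replicate %d", r))
  }
})

test_that("metrics report serializes to JSON", {
  tab <- make_toy_model_table(n_per_class = 20, seed = 13)
  b <- fit_scheme(tab, "tiered", split_protocol(seed = 13L))
  f <- tmp_path(".json")
  write_metrics_json(b$metrics, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$scheme, "tiered")
  expect_equal(back$overall$macro_accuracy, b$metrics$overall$macro_accuracy,
               tolerance = 1e-12)
  unlink(f)
})

test_that("degenerate inputs raise structured errors", {
  tab <- make_toy_model_table(n_per_class = 20, seed = 11)
  tab$score <- 0
  expect_error(fit_scheme(tab, "tiered", split_protocol(seed = 1L)),
               class = "tk_tier_degeneracy_error")
  tab2 <- make_toy_model_table(n_per_class = 20, seed = 11)
  b <- fit_scheme(tab2, "tiered", split_protocol(seed = 1L))
  one_class <- tab2[tab2$score == 2, ]
  expect_error(evaluate(b, one_class), class = "tk_undefined_metric_error")
  missing_col <- tab2[, setdiff(names(tab2), "mean_speed")]
  expect_error(predict_tiered(b, missing_col), class = "tk_schema_error")
})
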