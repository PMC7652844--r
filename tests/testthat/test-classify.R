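test_that("logistic fit recovers closed-form and oracle solutions", {
  # intercept-only: logit of the class rate
  f0 <- fit_logistic(matrix(nrow = 4, ncol = 0), c(1, 1, 1, 0))
  expect_equal(unname(f0$coefficients), log(3), tolerance = 1e-8)
  # constant feature, balanced classes: no information
  f1 <- fit_logistic(rep(2, 8), c(1, 0, 1, 0, 1, 0, 1, 0))
  expect_lt(max(abs(f1$coefficients)), 1e-6)
  # small fixture against the independent Newton-Raphson oracle
  x <- c(1, 2, 3, 4)
  y <- c(0, 1, 0, 1)
  f2 <- fit_logistic(x, y)
  expect_lt(max(abs(f2$coefficients - newton_logistic_oracle(x, y))), 1e-6)
  expect_error(fit_logistic(x, c(1, 1, 1, 1)), class = "degenerate_labels")
})

test_that("separation is detected and resolved with a tiny ridge", {
  f <- fit_logistic(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_true(f$separable)
  expect_true(all(is.finite(f$coefficients)))
  p <- predict(f, c(1, 12))
  expect_lt(p[1], 0.01)
  expect_gt(p[2], 0.99)
})

test_that("ROC curves honor the ties and endpoint conventions", {
  # perfect separation passes through (0, 1)
  c1 <- roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0), positive_class = 1)
  expect_true(any(c1$fpr == 0 & c1$tpr == 1))
  expect_equal(auc(c1), 1)
  # all-tied scores: single diagonal step
  c2 <- roc_curve(rep(1, 6), c(1, 1, 1, 0, 0, 0), positive_class = 1)
  expect_equal(auc(c2), 0.5)
  expect_equal(nrow(c2), 2)
  # worked example: 3 of 4 pairs concordant
  c3 <- roc_curve(c(0.9, 0.3, 0.5, 0.1), c("m", "m", "f", "f"),
                  positive_class = "m")
  expect_equal(auc(c3), 0.75)
  # curve shape invariants
  expect_true(all(diff(c3$fpr) >= 0) && all(diff(c3$tpr) >= 0))
  expect_true(all(diff(c3$threshold) < 0))
  expect_error(roc_curve(1:3, c(1, 1, 1), positive_class = 1),
               class = "degenerate_labels")
})

test_that("trapezoid AUC equals the rank-statistic AUC", {
  set.seed(42)
  for (i in 1:25) {
    n <- 50
    y <- rbinom(n, 1, 0.45)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n, mean = y), sample(c(1, 2, 8), 1))  # induces ties
    expect_lt(abs(auc(roc_curve(s, y, positive_class = 1)) -
                    mw_auc_oracle(s, y)), 1e-12)
  }
})

test_that("AUC respects monotone transforms and label flips", {
  set.seed(7)
  y <- rep(c(0, 1), each = 25)
  s <- rnorm(50, mean = y)
  a <- auc(roc_curve(s, y, positive_class = 1))
  for (f in list(function(z) 3 * z + 2, exp, function(z) plogis(z / 2))) {
    expect_equal(auc(roc_curve(f(s), y, positive_class = 1)), a,
                 tolerance = 1e-12)
  }
  expect_equal(auc(roc_curve(s, 1 - y, positive_class = 1)), 1 - a,
               tolerance = 1e-12)
  # feasibility of the accuracy constraint is monotone-invariant too
  r1 <- constrained_max_accuracy(s, y, positive_class = 1)
  r2 <- constrained_max_accuracy(exp(s), y, positive_class = 1)
  expect_equal(r1$accuracy, r2$accuracy)
})

test_that("constrained accuracy enforces strict TPR/FPR bounds", {
  res <- constrained_max_accuracy(c(0.9, 0.6, 0.5, 0.1), c("m", "m", "f", "f"),
                                  positive_class = "m")
  expect_equal(res$accuracy, 100)
  expect_true(res$threshold > 0.5 && res$threshold <= 0.6)
  # anti-separated: constraints cannot both hold
  anti <- constrained_max_accuracy(c(1, 2, 3, 4), c(1, 1, 0, 0),
                                   positive_class = 1)
  expect_false(anti$feasible)
  # all scores equal: TPR == FPR at every cut, strict bounds fail
  tied <- constrained_max_accuracy(rep(1, 6), c(1, 1, 1, 0, 0, 0),
                                   positive_class = 1)
  expect_false(tied$feasible)
})

test_that("balanced subsampling draws exact class counts and averages curves", {
  tab <- factor_feature_table(n = 120, n_female = 70, d = 3, seed = 2)
  y <- tab$sex
  x <- tab$mean_relative_beta
  cfg <- resample_config(n_iterations = 8, per_class_n = 20, seed = 3)
  b <- balanced_subsample_mean_roc(x, y, cfg)
  expect_length(b$auc_iterations, 8)
  expect_true(all(b$auc_iterations > 0.9))  # strong effect
  # single iteration: the mean curve is that iteration's curve
  cfg1 <- resample_config(n_iterations = 1, per_class_n = 20, seed = 3)
  b1 <- balanced_subsample_mean_roc(x, y, cfg1)
  expect_equal(b1$auc_mean_curve, b1$auc_iterations[1], tolerance = 0.02)
  # null features: chance level on average (cohort-level AUC noise shrinks
  # with n; subsample iterations share the cohort)
  tab0 <- factor_feature_table(n = 400, n_female = 200, d = 0, seed = 4)
  b0 <- balanced_subsample_mean_roc(tab0$mean_relative_beta, tab0$sex,
                                    resample_config(n_iterations = 100,
                                                    per_class_n = 40, seed = 5))
  expect_lt(abs(mean(b0$auc_iterations) - 0.5), 0.05)
  expect_error(balanced_subsample_mean_roc(x, y,
                                           resample_config(per_class_n = 60)),
               class = "config_error")
})

test_that("balanced subsampling is reproducible from the seed", {
  tab <- factor_feature_table(n = 100, n_female = 55, seed = 6)
  cfg <- resample_config(n_iterations = 5, per_class_n = 20, seed = 11)
  b1 <- balanced_subsample_mean_roc(tab$mean_relative_beta, tab$sex, cfg)
  b2 <- balanced_subsample_mean_roc(tab$mean_relative_beta, tab$sex, cfg)
  expect_identical(b1$auc_iterations, b2$auc_iterations)
})

test_that("leave-one-out covers every subject once and behaves at the extremes", {
  # complete separation with margin survives every fold
  x <- c(1:10, 21:30)
  y <- rep(c(0, 1), each = 10)
  s <- loocv_scores(x, y, positive_class = 1)
  expect_length(s, 20)
  expect_equal(auc(roc_curve(s, y, positive_class = 1)), 1)
  # permuted labels: chance level
  set.seed(8)
  xp <- rnorm(80)
  yp <- sample(rep(c(0, 1), each = 40))
  sp <- loocv_scores(xp, yp, positive_class = 1)
  expect_lt(abs(auc(roc_curve(sp, yp, positive_class = 1)) - 0.5), 0.1)
  expect_error(loocv_scores(1:6, c(1, 1, 0, 0, 0, 0), positive_class = 1),
               class = "degenerate_fold")
})

test_that("rank-based channel selection finds the informative channel", {
  set.seed(9)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 19), n, 19)
  x[, 7] <- x[, 7] + 2 * y
  expect_equal(rank_select_channels(x, y, 1, positive_class = 1), 7L)
  expect_true(7L %in% rank_select_channels(x, y, 3, positive_class = 1))
  expect_equal(rank_select_channels(x, y, 19, positive_class = 1), 1:19)
  expect_error(rank_select_channels(x, y, 0, positive_class = 1),
               class = "config_error")
  expect_error(rank_select_channels(x, y, 20, positive_class = 1),
               class = "config_error")
  # selection is computed on the supplied (training) rows only
  s1 <- rank_select_channels(x[-1, ], y[-1], 3, positive_class = 1)
  s2 <- rank_select_channels(x[-2, ], y[-2], 3, positive_class = 1)
  expect_length(s1, 3)
  expect_length(s2, 3)
})

test_that("evaluate_models reproduces the six-cell grid per session", {
  tab <- factor_feature_table(n = 110, n_female = 60, d = 4,
                              channel_noise = 0.01, seed = 10,
                              sessions = c("pre", "post"))
  grid <- evaluate_models(tab, resample_config(n_iterations = 4,
                                               per_class_n = 30, seed = 1))
  expect_equal(nrow(grid), 12)
  expect_setequal(unique(grid$scheme),
                  c("insample", "balanced", "loocv", "balanced+loocv"))
  # near-separable cohort: every AUC cell close to 1
  expect_true(all(grid$auc > 0.97))
})

test_that("in-sample multivariate fit is optimistic on null cohorts", {
  tab <- factor_feature_table(n = 90, n_female = 50, d = 0,
                              channel_noise = 1, seed = 12)
  y <- tab$sex
  x <- as.matrix(tab[, relbeta:::feature_channels(tab)])
  auc_in <- auc(roc_curve(predict(fit_logistic(x, encode <- as.numeric(y == "male")),
                                  x), y))
  auc_loo <- auc(roc_curve(loocv_scores(x, y), y))
  expect_gt(auc_in, auc_loo)
})
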