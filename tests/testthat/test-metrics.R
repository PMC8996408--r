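test_that("accuracy statistics match hand-computed examples exactly", {
  y <- c(1, 2, 3, 4); yh <- c(1.1, 1.9, 3.2, 3.8)
  # independent computation of the squared correlation from its definition
  num <- sum((y - mean(y)) * (yh - mean(yh)))^2
  den <- sum((y - mean(y))^2) * sum((yh - mean(yh))^2)
  expect_equal(r2(y, yh), num / den, tolerance = 1e-12)
  expect_equal(r2(y, y), 1)
  expect_equal(r2(y, 3 * y + 2), 1)            # affine invariance
  expect_equal(rmse(c(0, 0), c(3, -4)), 2.5 * sqrt(2), tolerance = 1e-12)
  expect_equal(mae(c(0, 0), c(3, -4)), 3.5)
  expect_equal(rmse(y, y), 0)
  expect_equal(mae(y, y), 0)
  expect_error(r2(rep(1, 5), 1:5), "constant")
  expect_error(rmse(1:3, 1:4))
  # sum-of-squares variant for sensitivity analysis
  expect_equal(r2(y, yh, method = "ss"),
               1 - sum((y - yh)^2) / sum((y - mean(y))^2))
})

test_that("RMSE dominates MAE on random data", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    y <- rnorm(n); yh <- rnorm(n)
    expect_gte(rmse(y, yh), mae(y, yh))
  }
})

test_that("cross-validated evaluation averages per-fold statistics", {
  X <- random_input_matrix(40, seed = 20)
  y <- 2 * X[, 1] + rnorm(40, 0, 0.1)
  Xte <- random_input_matrix(15, seed = 21)
  yte <- 2 * Xte[, 1]
  folds <- make_cv_folds(40, k = 4, seed = 5)
  rep <- evaluate_model(fit_mlr, X, y, Xte, yte, folds, "MLR")
  # independent recomputation of the CV average
  per <- sapply(folds, function(fold) {
    tr <- setdiff(1:40, fold)
    m <- fit_mlr(X[tr, ], y[tr])
    rmse(y[fold], predict(m, X[fold, , drop = FALSE]))
  })
  expect_equal(rep$train_rmse, mean(per), tolerance = 1e-12)
  expect_equal(rep$n_train, 40)
  expect_equal(rep$n_test, 15)
  expect_gte(rep$train_rmse, rep$train_mae * 0)  # sanity: all finite
})

test_that("a perfect oracle model scores perfectly", {
  X <- random_input_matrix(30, seed = 22)
  y <- 3 * X[, 2] + 1
  folds <- make_cv_folds(30, k = 3, seed = 1)
  # oracle "fit" returns the true law regardless of training data
  oracle_fit <- function(X, y)
    structure(list(intercept = 1, coefficients = c(0, 3, rep(0, 7))),
              class = "mlr_model")
  Xte <- random_input_matrix(10, seed = 23)
  rep <- evaluate_model(oracle_fit, X, y, Xte, 3 * Xte[, 2] + 1, folds,
                        "oracle")
  expect_equal(rep$test_rmse, 0, tolerance = 1e-12)
  expect_equal(rep$train_r2, 1, tolerance = 1e-12)
})

test_that("fold leakage is rejected", {
  X <- random_input_matrix(20, seed = 24)
  y <- rnorm(20)
  folds <- list(1:10, c(11:19, 25))  # index 25 is outside the training set
  expect_error(evaluate_model(fit_mlr, X[1:20, ], y, X[1:5, ], y[1:5],
                              folds), "leakage")
})

test_that("observed-vs-predicted export carries the fitted line", {
  d <- expand_replicates(packaged_design("Chandler"), seed = 30)
  X <- as.matrix(d[paste0("X", 1:9)])
  m <- fit_mlr(X, d$PR)
  ex <- export_obs_vs_pred(m, d, "PR")
  expect_equal(nrow(ex), 224)
  fit <- lm(ex$predicted ~ ex$observed)
  expect_equal(attr(ex, "slope"), unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(attr(ex, "intercept"), unname(coef(fit)[1]),
               tolerance = 1e-12)
  # a perfect model exports the identity line (a deterministic response so
  # the 1-nearest-neighbour lookup is exact even across duplicated inputs)
  d$PR <- drop(X %*% seq(0.1, 0.9, by = 0.1)) + 2
  oracle <- fit_knn(X, d$PR, k = 1)
  ex2 <- export_obs_vs_pred(oracle, d, "PR")
  expect_equal(attr(ex2, "slope"), 1, tolerance = 1e-9)
  expect_equal(attr(ex2, "intercept"), 0, tolerance = 1e-9)
})
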