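test_that("OLS recovers a noiseless linear law and matches normal equations", {
  X <- random_input_matrix(50, seed = 1)
  y <- 1 + 2 * X[, 1]
  m <- fit_mlr(X, y)
  expect_equal(m$intercept, 1, tolerance = 1e-10)
  expect_equal(m$coefficients, c(2, rep(0, 8)), tolerance = 1e-10)
  # independent normal-equations oracle on noisy data
  set.seed(2)
  y2 <- 3 - X[, 2] + 0.5 * X[, 5] + rnorm(50, 0, 0.3)
  m2 <- fit_mlr(X, y2)
  A <- cbind(1, X)
  beta <- solve(t(A) %*% A, t(A) %*% y2)
  expect_equal(c(m2$intercept, m2$coefficients), drop(beta),
               tolerance = 1e-8, ignore_attr = TRUE)
  # residual orthogonality
  res <- y2 - predict(m2, X)
  expect_lt(max(abs(t(A) %*% res)), 1e-8)
  # constant target: intercept is the mean, slopes vanish
  m3 <- fit_mlr(X, rep(4.2, 50))
  expect_equal(m3$intercept, 4.2, tolerance = 1e-10)
  expect_equal(m3$coefficients, rep(0, 9), tolerance = 1e-10)
  # rank deficiency names the collinear column
  Xd <- X; Xd[, 9] <- Xd[, 1]
  expect_error(fit_mlr(Xd, y2), "collinear")
})

test_that("KNN limiting cases hold exactly", {
  X <- random_input_matrix(20, seed = 3)
  y <- rnorm(20)
  m1 <- fit_knn(X, y, k = 1)
  expect_equal(predict(m1, X), y)
  mn <- fit_knn(X, y, k = 20)
  expect_equal(predict(mn, X[1:3, ]), rep(mean(y), 3))
  expect_error(fit_knn(X, y, k = 21), "k exceeds")
})

test_that("KNN predictions match a brute-force neighbour search", {
  # 3-point toy set with an equidistant query: tie goes to the earlier record
  Xt <- rbind(c(0, 0), c(2, 0), c(1, 5))
  Xt <- cbind(Xt, matrix(0, 3, 7))
  y <- c(10, 20, 60)
  m <- fit_knn(Xt, y, k = 2)
  q <- matrix(c(1, 0, rep(0, 7)), 1)  # equidistant from points 1 and 2
  expect_equal(predict(m, q), mean(c(10, 20)))
  # randomized equivalence across all four metrics
  set.seed(8)
  Xt2 <- random_input_matrix(15)
  y2 <- rnorm(15)
  Q <- random_input_matrix(6)
  for (metric in c("euclidean", "manhattan", "chebyshev", "minkowski")) {
    m2 <- fit_knn(Xt2, y2, k = 4, metric = metric)
    brute <- apply(Q, 1, function(q) {
      d <- apply(Xt2, 1, function(t) {
        dd <- abs(q - t)
        switch(metric, euclidean = sqrt(sum(dd^2)),
               manhattan = sum(dd), chebyshev = max(dd),
               minkowski = sum(dd^3)^(1 / 3))
      })
      mean(y2[order(d)[1:4]])
    })
    expect_equal(predict(m2, Q), brute, tolerance = 1e-12)
  }
})

test_that("KNN selection finds a pure-lookup structure at k = 1", {
  # pure-lookup structure: every input occurs twice with an identical
  # target, so the single nearest neighbour (the duplicate) is exact while
  # any wider neighbourhood mixes in unrelated targets
  set.seed(5)
  Xu <- random_input_matrix(30)
  yu <- rnorm(30, sd = 5)
  X <- rbind(Xu, Xu)
  y <- c(yu, yu)
  folds <- make_cv_folds(60, k = 5, seed = 2)
  sel <- select_knn(X, y, folds, k_grid = 1:8)
  expect_equal(sel$k, 1)
  expect_error(select_knn(X, y, folds, k_grid = integer(0)), "empty")
})

test_that("KNN selection drifts to large k on pure noise", {
  folds_seed <- 11
  big <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    X <- random_input_matrix(50)
    y <- rnorm(50)
    folds <- make_cv_folds(50, k = 5, seed = folds_seed)
    sel <- select_knn(X, y, folds, k_grid = 1:12,
                      metrics = "euclidean")
    if (sel$k >= 6) big <- big + 1
  }
  expect_gte(big, 8)
})

test_that("perceptron forward pass and determinism contracts hold", {
  X <- random_input_matrix(30, seed = 6)
  y <- X[, 1]
  m1 <- fit_mlpnn(X, y, H = 2, seed = 4, restarts = 2, maxit = 50)
  m2 <- fit_mlpnn(X, y, H = 2, seed = 4, restarts = 2, maxit = 50)
  expect_identical(m1$pars, m2$pars)
  expect_equal(m1$architecture, "9-2-1")
  # zero weights: output equals the output bias everywhere
  m0 <- m1
  m0$pars$W1[] <- 0; m0$pars$b1[] <- 0; m0$pars$w2[] <- 0; m0$pars$b2 <- 1.5
  expect_equal(predict(m0, X), rep(1.5, 30))
})

test_that("a small perceptron masters a noiseless one-factor task", {
  Xtr <- random_input_matrix(80, seed = 7)
  Xte <- random_input_matrix(40, seed = 8)
  m <- fit_mlpnn(Xtr, Xtr[, 1], H = 1, seed = 1, restarts = 5, maxit = 300)
  expect_lt(rmse(Xte[, 1], predict(m, Xte)), 0.05)
})

test_that("perceptron selection prefers the smallest adequate network", {
  set.seed(9)
  X <- random_input_matrix(40)
  y <- 2 * X[, 1] + 1
  folds <- make_cv_folds(40, k = 4, seed = 3)
  s1 <- select_mlpnn(X, y, folds, H_grid = c(1, 3), activations = "tanh",
                     seed = 10, restarts = 2, maxit = 150)
  s2 <- select_mlpnn(X, y, folds, H_grid = c(1, 3), activations = "tanh",
                     seed = 10, restarts = 2, maxit = 150)
  expect_identical(s1$pars, s2$pars)  # reproducible under a master seed
  expect_true(s1$H %in% c(1, 3))
  expect_equal(paste0("9-", s1$H, "-1"), s1$architecture)
})

test_that("baseline models serialize to JSON", {
  X <- random_input_matrix(20, seed = 10)
  y <- rnorm(20)
  f <- tempfile(fileext = ".json")
  write_baseline_model(fit_knn(X, y, 3, "manhattan"), f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$type, "knn")
  expect_equal(back$k, 3)
  write_baseline_model(fit_mlr(X, y), f)
  expect_equal(jsonlite::read_json(f, simplifyVector = TRUE)$type, "mlr")
})
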