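test_that("one swarm step matches the hand-rolled update equations", {
  lower <- rep(0, 2); upper <- rep(10, 2)
  obj <- function(X) rowSums((X - 3)^2)
  params <- pso_params(w = 0.9, c1 = 1.5, c2 = 1.0, swarm_size = 2,
                       iterations = 1, velocity_clamp = 0.5)
  X0 <- rbind(c(1, 2), c(6, 8))
  V0 <- rbind(c(0.5, -0.5), c(-1, 1))
  swarm <- list(X = X0, V = V0, pbest_X = rbind(c(2, 2), c(5, 7)),
                pbest_val = obj(rbind(c(2, 2), c(5, 7))),
                gbest_x = c(2, 2), gbest_val = obj(matrix(c(2, 2), 1)))
  r1 <- rbind(c(0.3, 0.7), c(0.1, 0.9))
  r2 <- rbind(c(0.6, 0.2), c(0.8, 0.4))
  out <- pso_step(swarm, params, obj, lower, upper, r1 = r1, r2 = r2)
  # hand computation: v' = w v + c1 r1 (p - x) + c2 r2 (g - x); x' = x + v'
  Vh <- 0.9 * V0 + 1.5 * r1 * (swarm$pbest_X - X0) +
    1.0 * r2 * (rbind(c(2, 2), c(2, 2)) - X0)
  Vh <- pmin(pmax(Vh, -5), 5)
  Xh <- pmin(pmax(X0 + Vh, 0), 10)
  expect_equal(out$X, Xh, tolerance = 1e-12)
  expect_equal(out$V, Vh, tolerance = 1e-12)
})

test_that("degenerate coefficients freeze the swarm", {
  obj <- function(X) rowSums(X^2)
  params <- pso_params(w = 0, c1 = 0, c2 = 0, swarm_size = 3,
                       iterations = 1)
  swarm <- list(X = matrix(1:6, 3, 2), V = matrix(0, 3, 2),
                pbest_X = matrix(1:6, 3, 2),
                pbest_val = obj(matrix(1:6, 3, 2)),
                gbest_x = c(1, 4), gbest_val = 17)
  out <- pso_step(swarm, params, obj, rep(-10, 2), rep(10, 2))
  expect_equal(out$X, swarm$X)
  expect_true(all(out$V == 0))
  # a single particle already at gbest with zero velocity is a fixed point
  one <- list(X = matrix(c(2, 2), 1), V = matrix(0, 1, 2),
              pbest_X = matrix(c(2, 2), 1), pbest_val = 8,
              gbest_x = c(2, 2), gbest_val = 8)
  p2 <- pso_params(w = 0.9, swarm_size = 1, iterations = 1)
  out2 <- pso_step(one, p2, obj, rep(-10, 2), rep(10, 2))
  expect_equal(out2$X, one$X)
})

test_that("the gbest trace is monotone and positions honour the bounds", {
  sph <- make_benchmark("sphere9")
  res <- pso_optimize(sph$fun, sph$lower, sph$upper,
                      pso_params(iterations = 200, seed = 3))
  expect_true(all(diff(res$trace) <= 0))
  expect_true(all(res$x >= sph$lower & res$x <= sph$upper))
  # determinism
  res2 <- pso_optimize(sph$fun, sph$lower, sph$upper,
                       pso_params(iterations = 200, seed = 3))
  expect_identical(res, res2)
  # collapsed bounds return the single feasible point
  point <- pso_optimize(sph$fun, rep(2, 9), rep(2, 9),
                        pso_params(iterations = 5, seed = 1))
  expect_equal(point$x, rep(2, 9))
})

test_that("scalarization respects direction, weights and dominance", {
  spec <- objective_spec("Chandler")
  ranges <- spec$ranges
  # the per-response ideal point scores exactly -w_PR
  ideal <- c(PR = ranges["PR", 2], CW = ranges["CW", 1],
             STN = ranges["STN", 1], Vit = ranges["Vit", 1])
  expect_equal(scalarize(ideal, spec), -1)
  # doubling the weights scales scores but never reorders candidates
  set.seed(12)
  P <- cbind(PR = runif(20, 4, 22), CW = runif(20, 0, 1),
             STN = runif(20, 10, 40), Vit = runif(20, 0, 35))
  s1 <- scalarize(P, spec)
  spec2 <- objective_spec("Chandler", weights = c(2, 2, 2, 2))
  expect_equal(scalarize(P, spec2), 2 * s1, tolerance = 1e-12)
  expect_equal(which.min(scalarize(P, spec2)), which.min(s1))
  # a medium dominating another on all four responses scores better
  for (i in 1:20) {
    a <- c(PR = 15, CW = 0.3, STN = 20, Vit = 10)
    b <- a + c(-1, 0.1, 2, 1)   # worse everywhere
    w <- runif(4, 0.1, 2)
    sp <- objective_spec("Chandler", weights = w)
    expect_lt(scalarize(a, sp), scalarize(b, sp))
  }
  expect_error(objective_spec(ranges = cbind(rep(1, 4), rep(1, 4))),
               "degenerate")
})

test_that("medium optimization improves on the DKW control and reports it", {
  surfaces <- get_equations("Chandler", substitute_F = TRUE)
  opt <- optimize_medium(surfaces, objective_spec("Chandler"),
                         params = pso_params(swarm_size = 30,
                                             iterations = 150, seed = 2))
  b <- factor_bounds()
  expect_true(all(opt$x >= b[, 1] & opt$x <= b[, 2]))
  expect_gt(opt$predictions["PR"], opt$dkw_predictions["PR"])
  expect_true(all(diff(opt$trace) <= 0))
  # determinism of the whole optimization
  opt2 <- optimize_medium(surfaces, objective_spec("Chandler"),
                          params = pso_params(swarm_size = 30,
                                              iterations = 150, seed = 2))
  expect_identical(opt$x, opt2$x)
})

test_that("the recipe report round-trips through CSV and text", {
  surfaces <- get_equations("Rayen", substitute_F = TRUE)
  opt <- optimize_medium(surfaces, objective_spec("Rayen"),
                         params = pso_params(swarm_size = 20,
                                             iterations = 60, seed = 4))
  rep <- report_optimum(opt)
  expect_setequal(rep$table$medium, c("Optimized", "DKW"))
  expect_true(any(grepl("NH4NO3", rep$text)))
  f <- tempfile(fileext = ".csv")
  write_recipe_csv(opt, f)
  back <- read_recipe_csv(f)
  expect_equal(back$x, opt$x)
  expect_equal(back$predictions, opt$predictions)
  expect_equal(back$dkw_predictions, opt$dkw_predictions)
})
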