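# Comparator regressors under the shared response-surface contract:
# ordinary least squares, k-nearest-neighbour regression with a choice of
# distance metrics, and a single-hidden-layer perceptron trained by BFGS.

KNN_METRICS <- c("euclidean", "manhattan", "chebyshev", "minkowski")

#' Fit a multiple linear regression surface
#'
#' Ordinary least squares of one response on the nine raw-scale factors
#' (linear models are scale-equivariant, so no normalization is applied).
#'
#' @param newdata training inputs: matrix or data frame with X1..X9.
#' @param y training targets.
#' @return An object of class \code{"mlr_model"} with \code{intercept} and
#'   \code{coefficients} (length 9).
#' @export
fit_mlr <- function(newdata, y) {
  X <- as_input_matrix(newdata)
  if (nrow(X) <= 10) stop("need more than 10 training rows")
  d <- data.frame(y = y, X)
  fit <- lm(y ~ ., data = d)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  structure(list(intercept = unname(cf[1]),
                 coefficients = unname(cf[-1]), lm = fit),
            class = "mlr_model")
}

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  X <- as_input_matrix(newdata)
  drop(object$intercept + X %*% object$coefficients)
}

knn_distances <- function(train_X, query_X, metric, p = 3) {
  n <- nrow(train_X); m <- nrow(query_X)
  D <- matrix(0, m, n)
  for (j in seq_len(ncol(train_X))) {
    diff <- abs(outer(query_X[, j], train_X[, j], "-"))
    D <- switch(metric,
      euclidean = D + diff^2,
      manhattan = D + diff,
      chebyshev = pmax(D, diff),
      minkowski = D + diff^p,
      stop("unknown metric: ", metric))
  }
  switch(metric, euclidean = sqrt(D), minkowski = D^(1 / p), D)
}

#' Fit a k-nearest-neighbour regression surface
#'
#' Memorizes the training set; prediction is the unweighted mean of the
#' targets of the k nearest training points under the chosen metric, with
#' distance ties broken by training-record order. Inputs are expected on a
#' commensurate scale (the packaged pipeline normalizes to the unit box).
#'
#' @param newdata training inputs (matrix or data frame with X1..X9).
#' @param y training targets.
#' @param k number of neighbours (1..n).
#' @param metric "euclidean", "manhattan", "chebyshev" or "minkowski".
#' @param p Minkowski exponent (default 3).
#' @return An object of class \code{"knn_model"}.
#' @export
fit_knn <- function(newdata, y, k, metric = "euclidean", p = 3) {
  X <- as_input_matrix(newdata)
  metric <- match.arg(metric, KNN_METRICS)
  stopifnot(k >= 1, p >= 1)
  if (k > nrow(X)) stop("k exceeds the number of training records")
  structure(list(X = X, y = y, k = k, metric = metric, p = p),
            class = "knn_model")
}

#' @export
predict.knn_model <- function(object, newdata, ...) {
  Q <- as_input_matrix(newdata)
  D <- knn_distances(object$X, Q, object$metric, object$p)
  apply(D, 1, function(d) {
    # order() is stable, so ties fall to the earlier training record
    nn <- order(d)[seq_len(object$k)]
    mean(object$y[nn])
  })
}

#' Select k and metric for KNN by cross-validation
#'
#' Grid search over k and the four distance metrics, scored by mean
#' validation RMSE over the folds; ties prefer the smaller k, then the
#' metric order euclidean, manhattan, chebyshev, minkowski.
#'
#' @param newdata training inputs.
#' @param y training targets.
#' @param folds fold index list from \code{\link{make_cv_folds}}.
#' @param k_grid candidate neighbour counts (default 1..15).
#' @param metrics candidate metrics (default all four).
#' @param p Minkowski exponent.
#' @return The winning \code{"knn_model"} fitted on the full training set,
#'   with attributes \code{cv_rmse}, \code{k} and \code{metric}.
#' @export
select_knn <- function(newdata, y, folds, k_grid = 1:15,
                       metrics = KNN_METRICS, p = 3) {
  if (length(k_grid) == 0 || length(metrics) == 0)
    stop("empty selection grid")
  X <- as_input_matrix(newdata)
  grid <- expand.grid(metric = metrics, k = k_grid,
                      stringsAsFactors = FALSE)
  # order so that the first minimum under ties is (smallest k, metric order)
  grid <- grid[order(grid$k, match(grid$metric, KNN_METRICS)), ]
  score <- vapply(seq_len(nrow(grid)), function(i) {
    k <- grid$k[i]; metric <- grid$metric[i]
    errs <- vapply(folds, function(fold) {
      tr <- setdiff(seq_len(nrow(X)), fold)
      if (k > length(tr)) return(NA_real_)
      m <- fit_knn(X[tr, , drop = FALSE], y[tr], k, metric, p)
      rmse(y[fold], predict(m, X[fold, , drop = FALSE]))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- which.min(score)
  model <- fit_knn(X, y, grid$k[best], grid$metric[best], p)
  attr(model, "cv_rmse") <- score[best]
  model
}

mlp_activation <- function(name) {
  switch(name,
    tanh = list(f = tanh, df = function(a) 1 - tanh(a)^2),
    logistic = list(f = function(a) 1 / (1 + exp(-a)),
                    df = function(a) { s <- 1 / (1 + exp(-a)); s * (1 - s) }),
    exponential = list(f = exp, df = exp),
    relu = list(f = function(a) pmax(a, 0), df = function(a) as.numeric(a > 0)),
    stop("unknown activation: ", name))
}

mlp_unpack <- function(theta, H, d = 9) {
  list(W1 = matrix(theta[seq_len(H * d)], H, d),
       b1 = theta[H * d + seq_len(H)],
       w2 = theta[H * d + H + seq_len(H)],
       b2 = theta[H * d + 2 * H + 1])
}

mlp_forward <- function(pars, X, act) {
  A <- X %*% t(pars$W1)
  A <- sweep(A, 2, pars$b1, "+")
  Z <- act$f(A)
  list(A = A, Z = Z, yhat = drop(Z %*% pars$w2) + pars$b2)
}

#' Fit a single-hidden-layer perceptron surface
#'
#' Architecture 9-H-1 with identity output; mean-squared-error loss
#' minimized by the BFGS quasi-Newton method with analytic gradients, from
#' seeded random initial weights; the best of \code{restarts} runs (by
#' training loss) is kept. Inputs are expected normalized to the unit box.
#'
#' @param newdata training inputs.
#' @param y training targets.
#' @param H hidden units (>= 1).
#' @param activation hidden activation: "tanh", "logistic", "exponential"
#'   or "relu".
#' @param seed RNG seed; the same (data, H, activation, seed) gives
#'   identical weights.
#' @param restarts random initializations (default 10).
#' @param maxit BFGS iteration cap per restart.
#' @return An object of class \code{"mlp_model"} with the weight matrices,
#'   the architecture label (e.g. "9-30-1") and the training record.
#' @export
fit_mlpnn <- function(newdata, y, H = 10, activation = "tanh", seed = NULL,
                      restarts = 10, maxit = 200) {
  X <- as_input_matrix(newdata)
  stopifnot(H >= 1, restarts >= 1)
  act <- mlp_activation(activation)
  n <- nrow(X)
  loss <- function(theta) {
    pars <- mlp_unpack(theta, H)
    mean((mlp_forward(pars, X, act)$yhat - y)^2)
  }
  grad <- function(theta) {
    pars <- mlp_unpack(theta, H)
    fw <- mlp_forward(pars, X, act)
    r <- 2 * (fw$yhat - y) / n            # d(MSE)/d(yhat)
    gw2 <- drop(crossprod(fw$Z, r))
    gb2 <- sum(r)
    dZ <- outer(r, pars$w2) * act$df(fw$A)
    gW1 <- crossprod(dZ, X)
    gb1 <- colSums(dZ)
    c(as.vector(gW1), gb1, gw2, gb2)
  }
  with_seed(seed, {
    best <- NULL
    converged <- FALSE
    for (rs in seq_len(restarts)) {
      theta0 <- c(rnorm(H * 9, 0, 0.5), rep(0, H), rnorm(H, 0, 0.5), mean(y))
      opt <- optim(theta0, loss, grad, method = "BFGS",
                   control = list(maxit = maxit))
      if (opt$convergence == 0) converged <- TRUE
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (!converged)
      warning("BFGS did not converge in any restart; best run returned")
    structure(list(pars = mlp_unpack(best$par, H), H = H,
                   activation = activation,
                   architecture = paste0("9-", H, "-1"),
                   final_loss = best$value, restarts = restarts),
              class = "mlp_model")
  })
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- as_input_matrix(newdata)
  mlp_forward(object$pars, X, mlp_activation(object$activation))$yhat
}

#' Select perceptron size and activation by cross-validation
#'
#' Grid search over hidden-layer sizes and activations scored by mean
#' validation RMSE over the folds; ties prefer the smaller H, then the
#' activation order as supplied.
#'
#' @param newdata training inputs.
#' @param y training targets.
#' @param folds fold index list from \code{\link{make_cv_folds}}.
#' @param H_grid candidate hidden sizes (default spans the architectures
#'   used in the packaged comparison).
#' @param activations candidate activations.
#' @param seed master seed; each fit receives a derived sub-seed so the
#'   search is reproducible.
#' @param restarts,maxit passed to \code{\link{fit_mlpnn}}.
#' @return The winning \code{"mlp_model"} refitted on the full training
#'   set, with attribute \code{cv_rmse}.
#' @export
select_mlpnn <- function(newdata, y, folds,
                         H_grid = c(5, 10, 12, 15, 20, 30, 40),
                         activations = c("tanh", "logistic", "exponential",
                                         "relu"),
                         seed = NULL, restarts = 3, maxit = 200) {
  stopifnot(length(H_grid) > 0)
  X <- as_input_matrix(newdata)
  H_grid <- sort(H_grid)
  grid <- expand.grid(activation = activations, H = H_grid,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$H, match(grid$activation, activations)), ]
  score <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- vapply(seq_along(folds), function(fi) {
      fold <- folds[[fi]]
      tr <- setdiff(seq_len(nrow(X)), fold)
      m <- fit_mlpnn(X[tr, , drop = FALSE], y[tr], grid$H[i],
                     grid$activation[i],
                     seed = if (is.null(seed)) NULL else seed + 1000 * i + fi,
                     restarts = restarts, maxit = maxit)
      rmse(y[fold], predict(m, X[fold, , drop = FALSE]))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- which.min(score)
  model <- fit_mlpnn(X, y, grid$H[best], grid$activation[best],
                     seed = if (is.null(seed)) NULL else seed + 999,
                     restarts = restarts, maxit = maxit)
  attr(model, "cv_rmse") <- score[best]
  model
}

#' Serialize a baseline model to JSON
#' @param model an \code{"mlr_model"}, \code{"knn_model"} or
#'   \code{"mlp_model"}.
#' @param path output file path.
#' @export
write_baseline_model <- function(model, path) {
  obj <- if (inherits(model, "mlr_model")) {
    list(type = "mlr", intercept = model$intercept,
         coefficients = model$coefficients)
  } else if (inherits(model, "knn_model")) {
    list(type = "knn", k = model$k, metric = model$metric, p = model$p,
         X = model$X, y = model$y)
  } else if (inherits(model, "mlp_model")) {
    list(type = "mlpnn", architecture = model$architecture,
         activation = model$activation, W1 = model$pars$W1,
         b1 = model$pars$b1, w2 = model$pars$w2, b2 = model$pars$b2)
  } else stop("unknown model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
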