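# Model accuracy statistics and the cross-validated comparison protocol:
# tenfold-CV training statistics plus held-out test statistics per model,
# and observed-vs-predicted exports for plotting.

#' Coefficient of determination
#'
#' By default the squared sample Pearson correlation of observed and
#' predicted values (the form used by the packaged comparison protocol);
#' \code{method = "ss"} gives the sum-of-squares form 1 - SSE/SST for
#' sensitivity analysis.
#'
#' @param observed,predicted equal-length numeric vectors, n >= 3.
#' @param method "pearson" (default) or "ss".
#' @return For "pearson", a value in [0, 1].
#' @export
r2 <- function(observed, predicted, method = c("pearson", "ss")) {
  method <- match.arg(method)
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (method == "ss")
    return(1 - sum((observed - predicted)^2) /
             sum((observed - mean(observed))^2))
  if (sd(observed) == 0 || sd(predicted) == 0)
    stop("constant series; squared correlation undefined")
  cor(observed, predicted)^2
}

#' Root mean squared error
#' @param observed,predicted equal-length numeric vectors.
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  sqrt(mean((observed - predicted)^2))
}

#' Mean absolute error
#' @param observed,predicted equal-length numeric vectors.
#' @export
mae <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  mean(abs(observed - predicted))
}

#' Cross-validated train statistics plus held-out test statistics
#'
#' Training statistics are the unweighted mean of per-fold validation
#' statistics: for each fold the model is refitted on the remaining
#' training records and scored on the held-out fold. Test statistics are
#' computed once, from the model fitted on the full training set, on the
#' untouched test set.
#'
#' @param fit_fun function(X, y) returning a model with a \code{predict}
#'   method over X1..X9 rows.
#' @param train_X,train_y training inputs/targets.
#' @param test_X,test_y held-out test inputs/targets.
#' @param folds fold index list over the training rows
#'   (\code{\link{make_cv_folds}}); indices beyond the training set are a
#'   leakage error.
#' @param label model label for the report row.
#' @return One-row data frame: label, train_rmse, train_mae, train_r2,
#'   test_rmse, test_mae, test_r2, n_train, n_test.
#' @export
evaluate_model <- function(fit_fun, train_X, train_y, test_X, test_y,
                           folds, label = "model") {
  train_X <- as_input_matrix(train_X)
  test_X <- as_input_matrix(test_X)
  n <- nrow(train_X)
  if (any(unlist(folds) > n) || any(unlist(folds) < 1))
    stop("fold leakage: fold indices outside the training set")
  per_fold <- t(vapply(folds, function(fold) {
    tr <- setdiff(seq_len(n), fold)
    m <- fit_fun(train_X[tr, , drop = FALSE], train_y[tr])
    p <- predict(m, train_X[fold, , drop = FALSE])
    c(rmse(train_y[fold], p), mae(train_y[fold], p),
      r2(train_y[fold], p))
  }, numeric(3)))
  final <- fit_fun(train_X, train_y)
  pt <- predict(final, test_X)
  data.frame(
    label = label,
    train_rmse = mean(per_fold[, 1]), train_mae = mean(per_fold[, 2]),
    train_r2 = mean(per_fold[, 3]),
    test_rmse = rmse(test_y, pt), test_mae = mae(test_y, pt),
    test_r2 = r2(test_y, pt),
    n_train = n, n_test = nrow(test_X),
    stringsAsFactors = FALSE
  )
}

derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 97 + k * 7919) %% (2^31 - 1)) + 1L
}

#' Model-comparison report for one genotype
#'
#' Reproduces the four-model comparison protocol on a replicate-level
#' dataset: 70/30 record-level split, tenfold cross-validation on the
#' training records, and per-response fits of MLR (raw inputs), KNN,
#' MLPNN and GEP (unit-box-normalized inputs). KNN and MLPNN rows carry
#' the selected hyperparameter annotation, e.g. "KNN (4)" and
#' "MLPNN (9-15-1)".
#'
#' @param genotype "Chandler" or "Rayen".
#' @param data replicate-level data frame; generated from the packaged
#'   design via \code{\link{expand_replicates}} when NULL.
#' @param seed master seed; every randomized stage receives a derived
#'   sub-seed, so the report is deterministic.
#' @param responses responses to model (default all four).
#' @param knn_k_grid,knn_metrics KNN selection grid.
#' @param mlp_H_grid,mlp_activations,mlp_restarts,mlp_maxit perceptron
#'   budget; the defaults are deliberately small so a full report runs in
#'   minutes.
#' @param gep_generations GEP budget per cross-validation fold refit.
#' @param gep_final_generations GEP budget for the final model fitted on
#'   the full training set (the model scored on the test set), where a
#'   longer run pays off most.
#' @return Data frame with one row per model x response: model, response,
#'   label, the six statistics of \code{\link{evaluate_model}}, n_train,
#'   n_test.
#' @export
comparison_report <- function(genotype, data = NULL, seed = 1,
                              responses = RESPONSES,
                              knn_k_grid = 1:15, knn_metrics = KNN_METRICS,
                              mlp_H_grid = 15, mlp_activations = "tanh",
                              mlp_restarts = 2, mlp_maxit = 150,
                              gep_generations = 300,
                              gep_final_generations = 1200) {
  if (is.null(data))
    data <- expand_replicates(packaged_design(genotype), seed = derive_seed(seed, 1))
  split <- split_train_test(data, seed = derive_seed(seed, 2))
  folds <- make_cv_folds(nrow(split$train), k = 10,
                         seed = derive_seed(seed, 3))
  Xtr_raw <- as_input_matrix(split$train)
  Xte_raw <- as_input_matrix(split$test)
  Xtr <- as_input_matrix(normalize_factors(Xtr_raw, clamp = TRUE))
  Xte <- as_input_matrix(normalize_factors(Xte_raw, clamp = TRUE))
  gcfg <- gep_config(generations = gep_generations,
                     stall_generations = gep_generations)
  gcfg_final <- gep_config(generations = gep_final_generations,
                           stall_generations = gep_final_generations)
  rows <- list()
  for (resp in responses) {
    ytr <- split$train[[resp]]; yte <- split$test[[resp]]
    rows[[length(rows) + 1]] <- cbind(
      model = "MLR", response = resp,
      evaluate_model(fit_mlr, Xtr_raw, ytr, Xte_raw, yte, folds, "MLR"))
    knn_sel <- select_knn(Xtr, ytr, folds, k_grid = knn_k_grid,
                          metrics = knn_metrics)
    knn_fit <- function(X, y) fit_knn(X, y, knn_sel$k, knn_sel$metric,
                                      knn_sel$p)
    rows[[length(rows) + 1]] <- cbind(
      model = "KNN", response = resp,
      evaluate_model(knn_fit, Xtr, ytr, Xte, yte, folds,
                     paste0("KNN (", knn_sel$k, ")")))
    if (length(mlp_H_grid) > 1 || length(mlp_activations) > 1) {
      mlp_sel <- select_mlpnn(Xtr, ytr, folds, H_grid = mlp_H_grid,
                              activations = mlp_activations,
                              seed = derive_seed(seed, 4),
                              restarts = mlp_restarts, maxit = mlp_maxit)
      H <- mlp_sel$H; act <- mlp_sel$activation
    } else {
      H <- mlp_H_grid[1]; act <- mlp_activations[1]
    }
    mlp_i <- 0
    mlp_fit <- function(X, y) {
      mlp_i <<- mlp_i + 1
      fit_mlpnn(X, y, H, act, seed = derive_seed(seed, 40 + mlp_i),
                restarts = mlp_restarts, maxit = mlp_maxit)
    }
    rows[[length(rows) + 1]] <- cbind(
      model = "MLPNN", response = resp,
      evaluate_model(mlp_fit, Xtr, ytr, Xte, yte, folds,
                     paste0("MLPNN (9-", H, "-1)")))
    # fold refits use the working budget; the final fit (the one scored on
    # the test set and exported) gets the full budget
    gep_i <- 0
    gep_fit <- function(X, y) {
      gep_i <<- gep_i + 1
      cfg_i <- if (gep_i > length(folds)) gcfg_final else gcfg
      evolve_gep(X, y, cfg_i, seed = derive_seed(seed, 80 + gep_i))
    }
    rows[[length(rows) + 1]] <- cbind(
      model = "GEP", response = resp,
      evaluate_model(gep_fit, Xtr, ytr, Xte, yte, folds, "GEP"))
  }
  out <- do.call(rbind, rows)
  out <- cbind(genotype = genotype, out)
  rownames(out) <- NULL
  out
}

#' Observed-vs-predicted export for plotting
#'
#' Predicts every record of a replicate-level dataset and returns the
#' paired series together with the slope, intercept and R-squared of the
#' simple regression of predicted on observed (the fitted-line summary
#' shown on observed-vs-predicted panels).
#'
#' @param model any fitted surface with a \code{predict} method.
#' @param data replicate-level data frame.
#' @param response which response column the model predicts.
#' @param normalize_inputs normalize X1..X9 before prediction (use the
#'   same convention the model was trained with).
#' @return Data frame of (observed, predicted) with attributes
#'   \code{slope}, \code{intercept}, \code{r2}.
#' @export
export_obs_vs_pred <- function(model, data, response,
                               normalize_inputs = FALSE) {
  X <- as_input_matrix(data)
  if (normalize_inputs) X <- as_input_matrix(normalize_factors(X, clamp = TRUE))
  obs <- data[[response]]
  pred <- predict(model, X)
  fit <- lm(pred ~ obs)
  out <- data.frame(observed = obs, predicted = pred)
  attr(out, "slope") <- unname(coef(fit)[2])
  attr(out, "intercept") <- unname(coef(fit)[1])
  attr(out, "r2") <- r2(obs, pred)
  out
}
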