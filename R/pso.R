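# Bound-constrained particle swarm optimization and its application to the
# four response surfaces per genotype: maximize proliferation rate while
# minimizing callus weight, shoot tip necrosis and vitrification, via
# weighted-sum scalarization of min-max-normalized objectives.

#' PSO parameters
#'
#' Velocity update v' = w v + c1 r1 (pbest - x) + c2 r2 (gbest - x) with
#' fresh uniform r1, r2 per particle and dimension, followed by the
#' position update x' = x + v'. The inertia w must lie in [0.8, 1.2] and
#' the cognitive/social coefficients in [0, 2]; the default w = 0.8 (the
#' low end of that band) converges to machine precision on the sphere
#' benchmark where larger inertia stalls.
#'
#' @param w inertia coefficient.
#' @param c1,c2 cognitive and social coefficients.
#' @param swarm_size particles (>= 2).
#' @param iterations update steps.
#' @param velocity_clamp velocity bound as a fraction of each dimension's
#'   range.
#' @param seed RNG seed.
#' @return List of class \code{"pso_params"}.
#' @export
pso_params <- function(w = 0.8, c1 = 1.5, c2 = 1.5, swarm_size = 50,
                       iterations = 500, velocity_clamp = 0.5,
                       seed = NULL) {
  stopifnot(w >= 0.8 - 1e-12 || w == 0, c1 >= 0, c1 <= 2, c2 >= 0, c2 <= 2,
            swarm_size >= 1, iterations >= 1, velocity_clamp > 0)
  if (w != 0 && (w < 0.8 || w > 1.2))
    stop("inertia w must lie in [0.8, 1.2] (or be 0 for the degenerate case)")
  structure(list(w = w, c1 = c1, c2 = c2, swarm_size = swarm_size,
                 iterations = iterations, velocity_clamp = velocity_clamp,
                 seed = seed), class = "pso_params")
}

init_swarm <- function(objective, lower, upper, params) {
  d <- length(lower)
  X <- matrix(runif(params$swarm_size * d), params$swarm_size, d)
  X <- sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+")
  V <- matrix(0, params$swarm_size, d)
  val <- objective(X)
  val[!is.finite(val)] <- Inf
  g <- which.min(val)
  list(X = X, V = V, pbest_X = X, pbest_val = val,
       gbest_x = X[g, ], gbest_val = val[g])
}

#' One particle-swarm update step
#'
#' Applies the velocity and position updates to every particle: fresh
#' uniform r1, r2 per particle and dimension, velocity clamped to
#' +/- (velocity_clamp x range), position clipped to the bounds with the
#' velocity zeroed on any clipped dimension, then pbest/gbest refreshed
#' (lower objective is better; non-finite objective values are penalized
#' to +Inf).
#'
#' @param swarm swarm state list (\code{X}, \code{V}, \code{pbest_X},
#'   \code{pbest_val}, \code{gbest_x}, \code{gbest_val}).
#' @param params a \code{\link{pso_params}}.
#' @param objective function(matrix of rows) -> numeric scores.
#' @param lower,upper bound vectors.
#' @param r1,r2 optional pre-drawn random matrices (swarm x dimension) for
#'   auditing; fresh uniforms are drawn when NULL.
#' @return Updated swarm state.
#' @export
pso_step <- function(swarm, params, objective, lower, upper,
                     r1 = NULL, r2 = NULL) {
  n <- nrow(swarm$X); d <- ncol(swarm$X)
  if (is.null(r1)) r1 <- matrix(runif(n * d), n, d)
  if (is.null(r2)) r2 <- matrix(runif(n * d), n, d)
  G <- matrix(swarm$gbest_x, n, d, byrow = TRUE)
  V <- params$w * swarm$V +
    params$c1 * r1 * (swarm$pbest_X - swarm$X) +
    params$c2 * r2 * (G - swarm$X)
  vmax <- matrix(params$velocity_clamp * (upper - lower), n, d, byrow = TRUE)
  V <- pmin(pmax(V, -vmax), vmax)
  X <- swarm$X + V
  lo <- matrix(lower, n, d, byrow = TRUE)
  hi <- matrix(upper, n, d, byrow = TRUE)
  clipped <- X < lo | X > hi
  X <- pmin(pmax(X, lo), hi)
  V[clipped] <- 0
  val <- objective(X)
  val[!is.finite(val)] <- Inf
  improved <- val < swarm$pbest_val
  swarm$pbest_X[improved, ] <- X[improved, ]
  swarm$pbest_val[improved] <- val[improved]
  g <- which.min(swarm$pbest_val)
  swarm$X <- X; swarm$V <- V
  swarm$gbest_x <- swarm$pbest_X[g, ]
  swarm$gbest_val <- swarm$pbest_val[g]
  swarm
}

#' Minimize an objective over a box with PSO
#'
#' @param objective function(matrix of rows) -> numeric scores (lower is
#'   better); non-finite values are treated as +Inf.
#' @param lower,upper bound vectors (equal length).
#' @param params a \code{\link{pso_params}}.
#' @return List with \code{x} (best position), \code{value} (its score)
#'   and \code{trace} (gbest score per iteration, non-increasing).
#' @export
pso_optimize <- function(objective, lower, upper, params = pso_params()) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  with_seed(params$seed, {
    swarm <- init_swarm(objective, lower, upper, params)
    trace <- numeric(params$iterations)
    for (it in seq_len(params$iterations)) {
      swarm <- pso_step(swarm, params, objective, lower, upper)
      trace[it] <- swarm$gbest_val
    }
    list(x = swarm$gbest_x, value = swarm$gbest_val, trace = trace)
  })
}

#' Objective specification for medium optimization
#'
#' Direction per response (maximize PR; minimize CW, STN and Vit),
#' non-negative weights, and per-response min-max normalization ranges.
#' Ranges default to the observed span of the printed treatment means of
#' the packaged design for the given genotype, so all four responses are
#' scalarized on comparable scales.
#'
#' @param genotype genotype whose packaged design supplies default ranges.
#' @param weights named or positional weights for PR, CW, STN, Vit
#'   (default equal).
#' @param ranges optional 4 x 2 matrix (rows PR, CW, STN, Vit) of
#'   normalization ranges.
#' @param extrapolation_penalty weight of a small, bounded penalty on
#'   predictions outside the normalization range, keeping the recommended
#'   medium near response levels that were actually observed.
#' @return List of class \code{"objective_spec"}.
#' @export
objective_spec <- function(genotype = "Chandler", weights = c(1, 1, 1, 1),
                           ranges = NULL, extrapolation_penalty = 0.05) {
  stopifnot(length(weights) == 4, all(weights >= 0), sum(weights) > 0)
  if (is.null(ranges)) {
    d <- packaged_design(genotype)
    ranges <- t(vapply(RESPONSES, function(r)
      range(d[[paste0(r, "_mean")]]), numeric(2)))
  }
  ranges <- matrix(as.numeric(ranges), 4, 2,
                   dimnames = list(RESPONSES, c("min", "max")))
  if (any(ranges[, 2] <= ranges[, 1]))
    stop("degenerate normalization range")
  structure(list(
    directions = c(PR = "max", CW = "min", STN = "min", Vit = "min"),
    weights = stats::setNames(as.numeric(weights), RESPONSES),
    ranges = ranges,
    extrapolation_penalty = extrapolation_penalty
  ), class = "objective_spec")
}

#' Scalarize four response predictions (lower is better)
#'
#' Weighted sum of min-max-normalized objectives with maximized responses
#' negated: within the normalization ranges, a medium that dominates
#' another on all four responses always scores strictly better under
#' positive weights. Normalized objectives are saturated at [0, 1]: a
#' surface extrapolating far outside the observed response range (the
#' transcribed formulas are unbounded polynomials/trigonometrics) earns no
#' extra credit beyond the best observed level, which keeps the search
#' from being hijacked by one unbounded response.
#'
#' @param predictions matrix (rows = candidates) or vector with columns or
#'   names PR, CW, STN, Vit.
#' @param spec an \code{\link{objective_spec}}.
#' @return Numeric score vector.
#' @export
scalarize <- function(predictions, spec) {
  P <- if (is.matrix(predictions)) predictions else
    matrix(predictions, nrow = 1, dimnames = list(NULL, names(predictions)))
  P <- P[, RESPONSES, drop = FALSE]
  score <- 0
  for (r in RESPONSES) {
    z <- (P[, r] - spec$ranges[r, 1]) /
      (spec$ranges[r, 2] - spec$ranges[r, 1])
    # bounded penalty outside the observed span; zero within it
    excess <- pmin(pmax(z - 1, 0) + pmax(-z, 0), 10)
    z <- pmin(pmax(z, 0), 1)
    score <- score + spec$weights[r] *
      ((if (spec$directions[r] == "max") -z else z) +
         spec$extrapolation_penalty * excess)
  }
  unname(score)
}

DKW_CONTROL <- c(1, 1, 1, 1, 1, 1, 1, 1, 0.1)

predict_surfaces <- function(surfaces, X) {
  P <- vapply(RESPONSES, function(r) predict(surfaces[[r]], X),
              numeric(nrow(X)))
  matrix(P, nrow = nrow(X), dimnames = list(NULL, RESPONSES))
}

#' Optimize the medium composition over four response surfaces
#'
#' Runs seeded PSO over the continuous box spanned by the design factor
#' ranges, scalarizing the four surface predictions per
#' \code{\link{scalarize}}. Candidate media with a non-finite surface
#' value are penalized to +Inf (and counted). Returns the best-ever
#' medium, its four predictions, and the DKW-control baseline predictions
#' from the same surfaces.
#'
#' @param surfaces named list (PR, CW, STN, Vit) of objects with a
#'   \code{predict} method over raw-scale X1..X9 rows (e.g.
#'   \code{\link{get_equations}} with \code{substitute_F = TRUE}).
#' @param spec an \code{\link{objective_spec}}.
#' @param bounds 9 x 2 matrix of factor bounds (default
#'   \code{\link{factor_bounds}}).
#' @param params a \code{\link{pso_params}}.
#' @return Object of class \code{"optimized_medium"}: \code{x},
#'   \code{predictions}, \code{score}, \code{dkw_predictions},
#'   \code{trace}, \code{n_penalized}.
#' @export
optimize_medium <- function(surfaces, spec = objective_spec(),
                            bounds = factor_bounds(),
                            params = pso_params()) {
  stopifnot(all(RESPONSES %in% names(surfaces)))
  n_pen <- 0L
  objective <- function(X) {
    P <- predict_surfaces(surfaces, X)
    bad <- !is.finite(P)
    if (any(bad)) n_pen <<- n_pen + sum(rowSums(bad) > 0)
    s <- scalarize(P, spec)
    s[rowSums(bad) > 0] <- Inf
    s
  }
  res <- pso_optimize(objective, bounds[, 1], bounds[, 2], params)
  x <- stats::setNames(res$x, paste0("X", 1:9))
  pred <- drop(predict_surfaces(surfaces, matrix(res$x, 1)))
  dkw <- drop(predict_surfaces(surfaces, matrix(DKW_CONTROL, 1)))
  structure(list(x = x, predictions = pred, score = res$value,
                 dkw_predictions = dkw, trace = res$trace,
                 n_penalized = n_pen),
            class = "optimized_medium")
}

#' Recipe report for an optimized medium
#'
#' Emits the optimized and DKW-control rows as a data frame (factor
#' multipliers with component names, PGR doses in mg/l, and the four
#' predicted responses) plus human-readable text lines such as
#' "1.76 x NH4NO3, CaNO3, ZnNO3".
#'
#' @param result an \code{"optimized_medium"}.
#' @param digits rounding for the text rendering (the data frame keeps
#'   full precision).
#' @return List with \code{table} (data frame, rows Optimized and DKW) and
#'   \code{text} (character vector).
#' @export
report_optimum <- function(result, digits = 2) {
  fd <- factor_definitions()
  tab <- data.frame(
    medium = c("Optimized", "DKW"),
    rbind(result$x, DKW_CONTROL),
    rbind(result$predictions, result$dkw_predictions),
    row.names = NULL
  )
  names(tab) <- c("medium", paste0("X", 1:9), RESPONSES)
  txt <- c(
    "Optimized medium:",
    ifelse(fd$unit == "mg/l",
           paste0("  ", round(result$x, digits), " mg/l ", fd$components),
           paste0("  ", round(result$x, digits), " x ", fd$components)),
    sprintf("  predicted: PR %.2f, CW %.2f g, STN %.2f, Vit %.2f",
            result$predictions["PR"], result$predictions["CW"],
            result$predictions["STN"], result$predictions["Vit"]),
    sprintf("DKW control predicted: PR %.2f, CW %.2f g, STN %.2f, Vit %.2f",
            result$dkw_predictions["PR"], result$dkw_predictions["CW"],
            result$dkw_predictions["STN"], result$dkw_predictions["Vit"])
  )
  list(table = tab, text = txt)
}

#' Write and re-read a recipe table
#'
#' @param result an \code{"optimized_medium"}.
#' @param path CSV path.
#' @export
write_recipe_csv <- function(result, path) {
  write.csv(report_optimum(result)$table, path, row.names = FALSE)
  invisible(path)
}

#' Parse a recipe CSV back into an \code{"optimized_medium"} skeleton
#' @param path CSV path written by \code{\link{write_recipe_csv}}.
#' @return Object of class \code{"optimized_medium"} (without trace/score).
#' @export
read_recipe_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  opt <- tab[tab$medium == "Optimized", ]
  dkw <- tab[tab$medium == "DKW", ]
  structure(list(
    x = stats::setNames(as.numeric(opt[paste0("X", 1:9)]), paste0("X", 1:9)),
    predictions = stats::setNames(as.numeric(opt[RESPONSES]), RESPONSES),
    dkw_predictions = stats::setNames(as.numeric(dkw[RESPONSES]), RESPONSES)
  ), class = "optimized_medium")
}
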