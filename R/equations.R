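# The eight published GEP equations, transcribed into a versioned
# plain-text registry and exposed as evaluable response surfaces. Three of
# them contain tokens F1/F3/F4/F6/F8/F9 that are undefined in the source
# (most likely typesetting slips); those equations are flagged, and by
# default refuse to evaluate. An opt-in policy substitutes Fk -> Xk.

equations_registry_path <- function() {
  system.file("extdata", "gep_equations.json", package = "walnutmedia",
              mustWork = TRUE)
}

equations_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- jsonlite::read_json(equations_registry_path(),
                                    simplifyVector = TRUE)
    cache
  }
})

#' Retrieve a transcribed GEP equation
#'
#' @param genotype "Chandler" or "Rayen".
#' @param response "PR", "CW", "STN" or "Vit".
#' @param substitute_F resolve undefined F-tokens by the documented policy
#'   Fk -> Xk. The default (\code{FALSE}) keeps flagged equations literal,
#'   and prediction from them errors rather than silently guessing a model.
#' @return An object of class \code{"transcribed_eq"} with fields
#'   \code{genotype}, \code{response}, \code{terms} (the four gene
#'   sub-expressions), \code{flags} (unresolved-token notes) and
#'   \code{substituted}.
#' @export
get_equation <- function(genotype, response, substitute_F = FALSE) {
  genotype <- match.arg(genotype, GENOTYPES)
  response <- match.arg(response, RESPONSES)
  reg <- equations_registry()$equations
  i <- which(reg$genotype == genotype & reg$response == response)
  if (length(i) != 1) stop("no equation for ", genotype, " ", response)
  terms <- reg$terms[[i]]
  flags <- reg$flags[[i]]
  if (length(flags) > 0 && substitute_F)
    terms <- gsub("F([1-9])", "X\\1", terms)
  structure(list(genotype = genotype, response = response, terms = terms,
                 flags = flags, substituted = substitute_F),
            class = "transcribed_eq")
}

#' @export
print.transcribed_eq <- function(x, ...) {
  cat("Transcribed GEP equation:", x$genotype, x$response, "\n")
  if (length(x$flags) > 0)
    cat("flagged tokens:", paste(x$flags, collapse = ", "),
        if (x$substituted) "(substituted Fk -> Xk)" else "(literal)", "\n")
  for (t in x$terms) cat("  [", t, "]\n")
  invisible(x)
}

equation_formula <- function(eq) {
  paste0("[", eq$terms, "]", collapse = " + ")
}

#' Predict a response from a transcribed equation
#'
#' Evaluates the equation with protected operators (division by zero gives
#' 1, negative base with non-integer exponent uses the absolute base,
#' intermediates clamped to +/- 1e10). By default the equation is applied
#' to the raw-scale factor vector, the convention that reproduces the
#' published optimized-medium predictions; \code{normalize = TRUE} instead
#' maps the inputs to the unit box over the design factor ranges first
#' (the preprocessing used for model training), for sensitivity checks.
#'
#' @param object a \code{"transcribed_eq"}.
#' @param newdata 9-vector, matrix or data frame with X1..X9, raw scale.
#' @param normalize normalize inputs to [0, 1] before evaluation.
#' @param clamp passed to \code{\link{normalize_factors}} when normalizing
#'   (needed for the DKW control row).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.transcribed_eq <- function(object, newdata, normalize = FALSE,
                                   clamp = FALSE, ...) {
  if (length(object$flags) > 0 && !object$substituted)
    stop("equation ", object$genotype, " ", object$response,
         " contains unresolved tokens (",
         paste(object$flags, collapse = ", "),
         "); re-fetch with substitute_F = TRUE to apply the Fk -> Xk policy")
  X <- as_input_matrix(newdata)
  if (normalize)
    X <- as_input_matrix(normalize_factors(X, clamp = clamp))
  fun <- gep_parse_formula(equation_formula(object))
  fun(X)
}

#' All four transcribed surfaces for one genotype
#'
#' Convenience wrapper used by the optimizer: returns the PR, CW, STN and
#' Vit equations as a named list. Flagged equations require
#' \code{substitute_F = TRUE} to be evaluable.
#'
#' @inheritParams get_equation
#' @return Named list of \code{"transcribed_eq"} objects.
#' @export
get_equations <- function(genotype, substitute_F = FALSE) {
  out <- lapply(RESPONSES, function(r)
    get_equation(genotype, r, substitute_F = substitute_F))
  names(out) <- RESPONSES
  out
}

#' Registry integrity checksum
#'
#' The transcriptions are frozen fixtures: any edit must bump the registry
#' version and changelog. Returns the md5 checksum of the registry file so
#' tests can pin it.
#' @return Named character checksum.
#' @export
equations_checksum <- function() {
  tools::md5sum(equations_registry_path())
}
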