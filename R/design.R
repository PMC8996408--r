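#' @useDynLib walnutmedia, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm optim predict rnorm runif sd var cor
#' @importFrom utils read.csv write.csv
NULL

GENOTYPES <- c("Chandler", "Rayen")
RESPONSES <- c("PR", "CW", "STN", "Vit")

#' Factor metadata for the walnut medium screening design
#'
#' Nine media factors were screened at three levels each: seven are
#' multipliers of component concentrations in the DKW (Driver-Kuniyuki
#' walnut) basal medium, and two are plant-growth-regulator doses in mg/l
#' (X8 = BAP; X9 = TDZ and IBA, dosed together).
#'
#' @return A data frame with one row per factor: \code{code} (X1..X9),
#'   \code{components} (chemical names), \code{level1..level3} (the three
#'   design levels, strictly increasing), and \code{unit}.
#' @export
factor_definitions <- function() {
  data.frame(
    code = paste0("X", 1:9),
    components = c(
      "NH4NO3, CaNO3, ZnNO3", "KNO3", "K2SO4",
      "MgSO4, MnSO4, CuSO4", "KH2PO4, H3BO3, Na2MoO4", "FeEDDHA",
      "Thiamine, Nicotinic acid, Glycine", "BAP", "TDZ, IBA"
    ),
    level1 = c(0.5, 0, 0, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    level2 = c(1.25, 1, 1, 1.5, 1.5, 1.25, 1.25, 1.25, 1.25),
    level3 = c(2, 2, 2, 2.5, 2.5, 2, 2, 2, 2),
    unit = c(rep("xDKW basal", 7), "mg/l", "mg/l"),
    stringsAsFactors = FALSE
  )
}

#' Factor bounds used for normalization and optimization
#'
#' @return A 9 x 2 matrix of per-factor (min, max) pairs, the extreme design
#'   levels of each factor. Row names are X1..X9.
#' @export
factor_bounds <- function() {
  fd <- factor_definitions()
  b <- cbind(min = fd$level1, max = fd$level3)
  rownames(b) <- fd$code
  b
}

# The realized design: 27 screening treatments plus the unmodified DKW
# control (all multipliers 1, X9 = 0.1 mg/l). Rows 12 and 13 are identical
# factor vectors, as realized in the experiment; the literal transcription
# is authoritative over any textbook array.
design_factor_matrix <- function() {
  x <- matrix(c(
    0.5,  2,    2,    2.5,  0.5,  0.5,  0.5,  2,    2,
    1.25, 2,    0,    1.5,  1.5,  2,    0.5,  0.5,  1.25,
    2,    2,    1,    0.5,  2.5,  1.25, 0.5,  1.25, 0.5,
    2,    1,    0,    2.5,  1.5,  0.5,  2,    2,    1.25,
    1.25, 0,    1,    2.5,  1.5,  2,    0.5,  1.25, 2,
    2,    0,    2,    1.5,  2.5,  1.25, 0.5,  2,    1.25,
    1.25, 2,    0,    1.5,  2.5,  0.5,  1.25, 1.25, 2,
    0.5,  2,    2,    2.5,  1.5,  1.25, 1.25, 0.5,  0.5,
    0.5,  1,    1,    1.5,  0.5,  0.5,  0.5,  1.25, 1.25,
    2,    2,    1,    0.5,  1.5,  0.5,  2,    0.5,  2,
    0.5,  0,    0,    0.5,  1.5,  1.25, 1.25, 1.25, 1.25,
    1.25, 1,    2,    0.5,  1.5,  2,    0.5,  2,    0.5,
    1.25, 1,    2,    0.5,  1.5,  2,    0.5,  2,    0.5,
    0.5,  0,    0,    0.5,  0.5,  0.5,  0.5,  0.5,  0.5,
    1.25, 0,    1,    2.5,  0.5,  1.25, 2,    0.5,  1.25,
    0.5,  0,    0,    0.5,  2.5,  2,    2,    2,    2,
    2,    1,    0,    2.5,  0.5,  2,    1.25, 1.25, 0.5,
    0.5,  1,    1,    1.5,  2.5,  2,    2,    0.5,  0.5,
    1.25, 1,    2,    0.5,  0.5,  1.25, 2,    1.25, 2,
    1.25, 1,    2,    0.5,  2.5,  0.5,  1.25, 0.5,  1.25,
    0.5,  1,    1,    1.5,  1.5,  1.25, 1.25, 2,    2,
    1.25, 0,    1,    2.5,  2.5,  0.5,  1.25, 2,    0.5,
    2,    2,    1,    0.5,  0.5,  2,    1.25, 2,    1.25,
    0.5,  2,    2,    2.5,  2.5,  2,    2,    1.25, 1.25,
    2,    0,    2,    1.5,  0.5,  2,    1.25, 0.5,  2,
    2,    1,    0,    2.5,  2.5,  1.25, 0.5,  0.5,  2,
    2,    0,    2,    1.5,  1.5,  0.5,  2,    1.25, 0.5,
    1,    1,    1,    1,    1,    1,    1,    1,    0.1
  ), ncol = 9, byrow = TRUE)
  colnames(x) <- paste0("X", 1:9)
  rownames(x) <- c(as.character(1:27), "DKW")
  x
}

# Response summaries (mean, SE over 8 replicate jars) per treatment, in row
# order 1..27 then DKW; columns PR, PR_se, CW, CW_se, STN, STN_se, Vit,
# Vit_se. Treatments 8, 9 and the DKW control showed no vitrification in
# Chandler (mean 0, no SE printed; transcribed as SE 0).
response_summary_matrix <- function(genotype) {
  chandler <- c(
    9.5, 0.18, 0.79, 0.01, 30.5, 0.9, 17.3, 0.32,
    8.1, 0.44, 0.20, 0.01, 20.3, 0.6, 11.7, 0.36,
    6.75, 0.2, 0.49, 0.02, 27.2, 0.4, 13.1, 0.44,
    10, 0.32, 0.89, 0.05, 31.2, 1.1, 12.8, 0.29,
    8.6, 0.18, 0.97, 0.06, 33.3, 1, 21.2, 0.45,
    7.3, 0.7, 1.09, 0.06, 30.1, 0.4, 29.1, 0.51,
    6.2, 0.31, 0.89, 0.01, 30.7, 0.7, 16.5, 0.32,
    10.5, 1.1, 0.28, 0.01, 20.2, 0.9, 0, 0,
    6.3, 0.3, 0.5, 0.01, 21, 0.8, 0, 0,
    10.7, 0.9, 0.99, 0.03, 36.1, 1.1, 11.5, 0.42,
    11.7, 1, 0.5, 0.01, 33.1, 0.9, 5.5, 0.32,
    10.5, 0.3, 0.49, 0.01, 39.3, 1.1, 10.7, 0.36,
    10, 0.32, 0.49, 0.01, 34.3, 0.8, 6.7, 0.35,
    4.8, 0.3, 0.24, 0.01, 20.6, 0.7, 4.6, 0.37,
    7.6, 0.18, 0.2, 0.01, 12.6, 0.6, 9.8, 0.39,
    5.7, 0.31, 0.89, 0.01, 31.6, 0.8, 27.1, 0.45,
    9.7, 0.28, 0.13, 0.01, 13.3, 0.3, 13.2, 0.33,
    6.7, 0.25, 0.18, 0.01, 11.3, 0.3, 3.8, 0.29,
    8, 0.32, 0.52, 0.01, 27.1, 0.5, 6.8, 0.25,
    7.3, 0.41, 0.20, 0.01, 15, 0.6, 6.8, 0.39,
    5.8, 0.3, 0.73, 0.01, 22, 0.5, 9.3, 0.32,
    9.1, 0.29, 0.2, 0.01, 15.7, 1, 7.1, 0.29,
    5.8, 0.3, 1.1, 0.03, 21.8, 0.6, 19.5, 0.32,
    21.8, 0.7, 0.09, 0.01, 11.1, 0.7, 3.1, 0.12,
    13.6, 0.3, 0.98, 0.01, 18.1, 0.8, 10.7, 0.45,
    12.1, 0.3, 0.8, 0.02, 13.6, 0.6, 9.7, 0.44,
    9.7, 0.31, 0.51, 0.01, 11.6, 0.6, 29, 0.46,
    7.12, 0.35, 0.3, 0.03, 10.75, 0.45, 0, 0
  )
  rayen <- c(
    8.5, 0.42, 0.92, 0.03, 33.8, 0.8, 21.7, 0.59,
    7.7, 0.31, 0.28, 0.02, 25.6, 1.1, 14, 0.26,
    6.3, 0.37, 0.48, 0.01, 49.5, 1.4, 15.7, 0.36,
    8, 0.37, 0.94, 0.02, 25.3, 1.5, 16.8, 0.29,
    7.7, 0.31, 0.99, 0.02, 27.2, 1.3, 27.7, 0.45,
    8, 0.32, 0.79, 0.03, 29.6, 0.6, 31.3, 0.54,
    5.8, 0.29, 1.07, 0.04, 31.2, 1, 17.3, 0.37,
    6.3, 0.26, 0.31, 0.01, 21.8, 1.1, 6, 0.46,
    6.3, 0.46, 0.52, 0.01, 27, 0.4, 6.2, 0.36,
    7, 0.53, 1.05, 0.04, 33.1, 1.2, 15, 0.37,
    8, 0.42, 0.45, 0.01, 28.5, 0.4, 8, 0.26,
    8.2, 0.49, 0.17, 0.01, 28, 0.6, 10.6, 0.46,
    9, 0.46, 0.39, 0.01, 27.3, 0.9, 9.2, 0.36,
    6.1, 0.39, 0.27, 0.01, 23.3, 0.5, 4, 0.26,
    7, 0.26, 0.29, 0.01, 21.7, 1.3, 12.1, 0.29,
    6, 0.46, 0.72, 0.02, 29, 1.5, 31.8, 0.44,
    7.3, 0.37, 0.26, 0.01, 18.1, 1.4, 16.1, 0.37,
    6.3, 0.53, 0.31, 0.01, 27.2, 1.3, 5, 0.32,
    7.5, 0.5, 0.46, 0.01, 27.8, 0.5, 7.1, 0.29,
    7.5, 0.32, 0.29, 0.01, 20.1, 0.6, 6.7, 0.25,
    6, 0.26, 0.94, 0.02, 27.1, 0.7, 10.7, 0.36,
    6.5, 0.32, 0.16, 0.01, 22, 0.9, 6, 0.37,
    6.6, 0.25, 0.91, 0.03, 27.2, 0.9, 22.5, 0.5,
    7, 0.31, 0.17, 0.01, 27.5, 0.6, 6, 0.26,
    10.2, 0.28, 0.55, 0.02, 21.6, 0.8, 9.3, 0.41,
    7.2, 0.36, 0.94, 0.03, 29.5, 0.7, 11.6, 0.37,
    8.3, 0.37, 0.46, 0.01, 27.3, 0.3, 35, 0.46,
    6.25, 0.4, 0.5, 0.06, 23.75, 0.59, 16.12, 1.1
  )
  v <- switch(genotype, Chandler = chandler, Rayen = rayen,
              stop("unknown genotype: ", genotype))
  m <- matrix(v, ncol = 8, byrow = TRUE)
  colnames(m) <- c("PR_mean", "PR_se", "CW_mean", "CW_se",
                   "STN_mean", "STN_se", "Vit_mean", "Vit_se")
  m
}

#' The realized walnut medium screening design with response summaries
#'
#' Returns the 27 screening treatments plus the DKW control for one
#' genotype, each as a 9-component factor vector together with the measured
#' response summaries (mean and standard error over 8 replicate jars) for
#' proliferation rate (PR, shoots per explant), callus weight (CW, g),
#' shoot tip necrosis (STN, %) and vitrification (Vit, %). Factor vectors
#' are identical for both genotypes; only the summaries differ.
#'
#' @param genotype "Chandler" or "Rayen".
#' @return A data frame with columns \code{genotype}, \code{treatment_id},
#'   \code{X1}..\code{X9}, and \code{<resp>_mean} / \code{<resp>_se} for each
#'   of the four responses. 28 rows.
#' @export
packaged_design <- function(genotype) {
  genotype <- match.arg(genotype, GENOTYPES)
  x <- design_factor_matrix()
  rs <- response_summary_matrix(genotype)
  out <- data.frame(
    genotype = genotype,
    treatment_id = rownames(x),
    x, rs,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' Generic L27 orthogonal array
#'
#' Builds the standard 27-run, 3-level orthogonal array L27(3^13) from the
#' three base-3 digits of the run index and assigns the requested number of
#' columns, mapped either to level indices 0/1/2 or to supplied factor
#' levels. Any two columns are pairwise orthogonal: each of the 9 level
#' pairs occurs exactly 3 times. Provided for reuse when re-running the
#' screening stage; the packaged design (\code{\link{packaged_design}}) is
#' the literal realized experiment and is used for all packaged analyses.
#'
#' @param n_factors number of columns to assign (1..13; default 9).
#' @param levels optional list of per-factor numeric level vectors
#'   (length 3 each); default maps to level indices 0, 1, 2.
#' @return A 27 x \code{n_factors} matrix.
#' @export
build_l27_array <- function(n_factors = 9, levels = NULL) {
  if (n_factors < 1 || n_factors > 13) stop("n_factors must be in 1..13")
  run <- 0:26
  a <- run %/% 9
  b <- (run %/% 3) %% 3
  d <- run %% 3
  # all 13 pairwise-independent linear combinations of the 3 base digits
  combos <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, 2, 0), c(1, 0, 1), c(1, 0, 2),
    c(0, 1, 1), c(0, 1, 2), c(1, 1, 1), c(1, 1, 2),
    c(1, 2, 1), c(1, 2, 2)
  )
  idx <- sapply(seq_len(n_factors), function(j) {
    (combos[j, 1] * a + combos[j, 2] * b + combos[j, 3] * d) %% 3
  })
  idx <- matrix(idx, nrow = 27)
  colnames(idx) <- paste0("X", seq_len(n_factors))
  if (is.null(levels)) return(idx)
  stopifnot(length(levels) == n_factors)
  out <- idx
  for (j in seq_len(n_factors)) {
    lv <- levels[[j]]
    stopifnot(length(lv) == 3)
    out[, j] <- lv[idx[, j] + 1]
  }
  out
}

#' Min-max normalizer over the design factor ranges
#'
#' @param bounds 9 x 2 matrix of (min, max) pairs; default
#'   \code{\link{factor_bounds}} (the design level extremes).
#' @return An object of class \code{"media_normalizer"}.
#' @export
media_normalizer <- function(bounds = factor_bounds()) {
  stopifnot(ncol(bounds) == 2)
  if (any(bounds[, 2] <= bounds[, 1]))
    stop("each factor must have max > min")
  structure(list(min = bounds[, 1], max = bounds[, 2]),
            class = "media_normalizer")
}

#' Normalize factor vectors to the unit box
#'
#' Component-wise (x - xmin) / (xmax - xmin). Inputs outside the normalizer
#' ranges are an error unless \code{clamp = TRUE}, in which case they are
#' clamped to the range with a warning (needed for the DKW control, whose
#' X9 = 0.1 mg/l lies below the design minimum of 0.5).
#'
#' @param x numeric 9-vector or matrix with 9 columns (raw factor scale).
#' @param norm a \code{\link{media_normalizer}}.
#' @param clamp clamp out-of-range inputs instead of erroring.
#' @return Same shape as \code{x}, values in [0, 1].
#' @export
normalize_factors <- function(x, norm = media_normalizer(), clamp = FALSE) {
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  stopifnot(ncol(xm) == length(norm$min))
  lo <- matrix(norm$min, nrow(xm), ncol(xm), byrow = TRUE)
  hi <- matrix(norm$max, nrow(xm), ncol(xm), byrow = TRUE)
  out_of_range <- xm < lo | xm > hi
  if (any(out_of_range)) {
    if (!clamp)
      stop("input outside normalizer range in factor(s): ",
           paste(unique(colnames(xm)[which(out_of_range, arr.ind = TRUE)[, 2]]),
                 collapse = ", "),
           " (use clamp = TRUE to clamp)")
    warning("clamping ", sum(out_of_range), " out-of-range value(s)")
    xm <- pmin(pmax(xm, lo), hi)
  }
  res <- (xm - lo) / (hi - lo)
  if (is.matrix(x)) res else drop(res)
}

#' Invert \code{\link{normalize_factors}}
#'
#' @inheritParams normalize_factors
#' @param z normalized values in [0, 1] (vector or matrix).
#' @export
denormalize_factors <- function(z, norm = media_normalizer()) {
  zm <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  lo <- matrix(norm$min, nrow(zm), ncol(zm), byrow = TRUE)
  hi <- matrix(norm$max, nrow(zm), ncol(zm), byrow = TRUE)
  res <- lo + zm * (hi - lo)
  if (is.matrix(z)) res else drop(res)
}

#' Export the packaged design as CSV
#'
#' Writes the design and summaries with columns genotype, treatment_id,
#' X1..X9 and the per-response mean/SE pairs, UTF-8 with "." decimals.
#'
#' @param genotype "Chandler" or "Rayen".
#' @param path output file path.
#' @export
write_design_csv <- function(genotype, path) {
  write.csv(packaged_design(genotype), path, row.names = FALSE)
  invisible(path)
}

#' Export factor metadata as JSON
#' @param path output file path.
#' @export
write_factor_json <- function(path) {
  jsonlite::write_json(factor_definitions(), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
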