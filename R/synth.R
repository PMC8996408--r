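# Replicate-level data synthesis from the printed per-treatment summaries,
# plus analytic benchmark surfaces for validating the GEP and PSO engines.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Expand response summaries into replicate-level records
#'
#' Each treatment's printed mean and standard error (over
#' \code{summary_reps} = 8 replicate jars) is expanded into \code{n_reps}
#' records by drawing from Normal(mean, SE * sqrt(summary_reps)) per
#' response — SE * sqrt(summary_reps) is the jar-level SD implied by a
#' standard error over 8 jars, independent of how many synthetic
#' replicates are drawn. With
#' \code{moment_match = TRUE} (default) the draws are affinely recentred and
#' rescaled so the sample mean equals the printed mean and the sample
#' standard error equals the printed SE exactly; draws producing any
#' negative response are rejected and redrawn (responses are counts, masses
#' and percentages, all non-negative). An SE of 0 yields constant
#' replicates.
#'
#' @param design a design data frame from \code{\link{packaged_design}}.
#' @param n_reps replicates drawn per treatment (default 8, as in the
#'   experiment).
#' @param summary_reps replicate count behind the printed SE values
#'   (8 jars); sets the jar-level SD.
#' @param seed RNG seed; generation is a pure function of
#'   (design, n_reps, seed, moment_match).
#' @param moment_match match first two moments exactly (default TRUE).
#' @param max_retry redraw cap per (treatment, response) before erroring.
#' @return A data frame with columns genotype, treatment_id, replicate,
#'   X1..X9, PR, CW, STN, Vit; \code{nrow = 28 * n_reps} (224 for the
#'   packaged design). Carries attributes \code{seed} and \code{n_reps}.
#' @export
expand_replicates <- function(design, n_reps = 8, seed = NULL,
                              moment_match = TRUE, max_retry = 100,
                              summary_reps = 8) {
  stopifnot(n_reps >= 2)
  need <- c(paste0("X", 1:9),
            as.vector(outer(RESPONSES, c("_mean", "_se"), paste0)))
  if (!all(need %in% names(design)))
    stop("design is missing columns: ",
         paste(setdiff(need, names(design)), collapse = ", "))
  with_seed(seed, {
    rows <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      resp <- matrix(NA_real_, n_reps, length(RESPONSES),
                     dimnames = list(NULL, RESPONSES))
      for (r in RESPONSES) {
        m <- design[[paste0(r, "_mean")]][i]
        se <- design[[paste0(r, "_se")]][i]
        sd_target <- se * sqrt(summary_reps)
        if (se == 0) {
          resp[, r] <- rep(m, n_reps)
          next
        }
        ok <- FALSE
        for (try in seq_len(max_retry)) {
          z <- rnorm(n_reps, m, sd_target)
          if (moment_match) {
            s <- sd(z)
            if (s == 0) next
            z <- m + (z - mean(z)) * sd_target / s
          } else {
            z <- pmax(z, 0)
          }
          if (all(z >= 0)) { ok <- TRUE; break }
        }
        if (!ok)
          stop("could not draw non-negative replicates for treatment ",
               design$treatment_id[i], ", response ", r)
        resp[, r] <- z
      }
      rows[[i]] <- data.frame(
        genotype = design$genotype[i],
        treatment_id = design$treatment_id[i],
        replicate = seq_len(n_reps),
        design[i, paste0("X", 1:9), drop = FALSE],
        resp, row.names = NULL, stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    if (any(out$CW > 10))
      warning("generated callus weight above 10 g; check summaries")
    attr(out, "seed") <- seed
    attr(out, "n_reps") <- n_reps
    out
  })
}

#' Split replicate records into training and test sets
#'
#' Records (not treatments) are sampled uniformly without replacement; the
#' training size is round-half-up(train_fraction * n), which reproduces the
#' 157/67 partition of 224 records at the default 70/30 split.
#'
#' @param data replicate-level data frame.
#' @param train_fraction fraction of records assigned to training
#'   (default 0.7).
#' @param seed RNG seed; the same seed always yields the same partition.
#' @return A list with elements \code{train} and \code{test} (data frames);
#'   attribute \code{train_idx} records the sampled row indices.
#' @export
split_train_test <- function(data, train_fraction = 0.7, seed = NULL) {
  n <- nrow(data)
  if (n == 0) stop("data is empty")
  stopifnot(train_fraction > 0, train_fraction < 1)
  n_train <- floor(train_fraction * n + 0.5)
  if (n_train == 0 || n_train == n)
    stop("train_fraction yields an empty train or test split")
  idx <- with_seed(seed, sample.int(n, n_train))
  out <- list(train = data[idx, , drop = FALSE],
              test = data[-idx, , drop = FALSE])
  attr(out, "train_idx") <- idx
  out
}

#' Partition a training set into k cross-validation folds
#'
#' Fold sizes differ by at most one (157 records at k = 10 give seven folds
#' of 16 and three of 15).
#'
#' @param n_train number of training records (or a data frame, in which case
#'   its row count is used).
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return A list of k integer vectors of row indices, pairwise disjoint,
#'   whose union is \code{1:n_train}.
#' @export
make_cv_folds <- function(n_train, k = 10, seed = NULL) {
  if (is.data.frame(n_train)) n_train <- nrow(n_train)
  stopifnot(k >= 2)
  if (k > n_train) stop("k exceeds the number of training records")
  perm <- with_seed(seed, sample.int(n_train))
  sizes <- rep(n_train %/% k, k)
  extra <- n_train %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  split(perm, rep(seq_len(k), sizes))
}

#' Analytic benchmark surfaces
#'
#' Known-formula response surfaces with seeded samples, used to validate the
#' symbolic-regression engine and the swarm optimizer against ground truth:
#' \describe{
#'   \item{sphere9}{f(x) = sum(x^2) on [-5, 5]^9; global minimum 0 at the
#'     origin (the centre of the domain).}
#'   \item{planted_linear}{y = 2 x1 - x2 + 0.5 on [0, 1]^9.}
#'   \item{planted_trig}{y = sin(3 x1) + 0.5 cos(2 x2) + x3 on [0, 1]^9.}
#' }
#'
#' @param name one of "sphere9", "planted_linear", "planted_trig".
#' @param n_sample number of sampled points (default 64).
#' @param seed RNG seed for the sample.
#' @return A list with \code{fun} (vectorized over a matrix of rows),
#'   \code{lower}, \code{upper} (domain bounds), \code{data} (data frame of
#'   X1..X9 and y), and for sphere9 \code{optimum} (the known minimum).
#' @export
make_benchmark <- function(name = c("sphere9", "planted_linear",
                                    "planted_trig"),
                           n_sample = 64, seed = 1) {
  name <- match.arg(name)
  spec <- switch(name,
    sphere9 = list(fun = function(X) rowSums(X^2),
                   lower = rep(-5, 9), upper = rep(5, 9), optimum = 0),
    planted_linear = list(
      fun = function(X) 2 * X[, 1] - X[, 2] + 0.5,
      lower = rep(0, 9), upper = rep(1, 9), optimum = NULL),
    planted_trig = list(
      fun = function(X) sin(3 * X[, 1]) + 0.5 * cos(2 * X[, 2]) + X[, 3],
      lower = rep(0, 9), upper = rep(1, 9), optimum = NULL)
  )
  X <- with_seed(seed, matrix(runif(n_sample * 9), n_sample, 9))
  X <- sweep(sweep(X, 2, spec$upper - spec$lower, "*"), 2, spec$lower, "+")
  colnames(X) <- paste0("X", 1:9)
  spec$data <- data.frame(X, y = spec$fun(X))
  spec$name <- name
  spec
}

#' Write a replicate-level dataset to CSV
#' @param data replicate data frame from \code{\link{expand_replicates}}.
#' @param path output file path.
#' @export
write_replicates_csv <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Read a replicate-level dataset from CSV
#' @param path input file path.
#' @export
read_replicates_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "treatment_id", "replicate", paste0("X", 1:9),
            RESPONSES)
  if (!all(need %in% names(d)))
    stop("replicate CSV is missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d
}
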