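# Gene expression programming: fixed-length multigenic Karva chromosomes
# decoded breadth-first into expression trees, evolved by roulette-wheel
# selection with elitism under the operator rates of the training protocol.

# symbol codes; must match src/gep_eval.cpp
GEP_FUNCTIONS <- data.frame(
  code = 1:9,
  name = c("+", "-", "*", "/", "sin", "cos", "sq", "cu", "pow"),
  arity = c(2, 2, 2, 2, 1, 1, 1, 1, 2),
  stringsAsFactors = FALSE
)
GEP_VAR0 <- 10L    # X_i has code 10 + i
GEP_CONST <- 20L
GEP_CLAMP <- 1e10

gep_arity <- function(code) {
  a <- integer(length(code))
  a[code %in% c(5L, 6L, 7L, 8L)] <- 1L
  a[code %in% c(1L, 2L, 3L, 4L, 9L)] <- 2L
  a
}

#' GEP training configuration
#'
#' Defaults follow the training protocol used for the packaged equations:
#' population of 50 chromosomes, head length 10, 4 genes linked by
#' addition, fitness from root relative squared error (RRSE), and operator
#' rates mutation 0.044, inversion 0.1, one-point recombination 0.1,
#' two-point recombination 0.3, gene recombination 0.1, gene transposition
#' 0.1. The tail length is h * (amax - 1) + 1 = 11 for maximum arity 2, so
#' genes are 21 symbols long. Ephemeral random constants uniform in
#' \code{constant_range} occupy terminal positions with probability
#' \code{constant_prob} and are redrawn or perturbed by mutation.
#'
#' @param population_size chromosomes per generation.
#' @param head_length gene head length h.
#' @param n_genes genes per chromosome (sub-trees linked by addition).
#' @param generations maximum generations.
#' @param mutation,inversion,one_point,two_point,gene_recomb,gene_transposition
#'   operator rates in [0, 1].
#' @param constant_range range of ephemeral random constants.
#' @param constant_prob probability that a random terminal is a constant.
#' @param elitism_count best individuals copied unchanged each generation.
#' @param immigrants random new chromosomes injected per generation (a
#'   continuous diversity source; 0 disables).
#' @param polish_constants constant-jitter proposals evaluated on the
#'   generation best each generation; improvements are kept (a memetic
#'   local search on the numeric constants; 0 disables).
#' @param linear_scaling fit the optimal output scale and offset by least
#'   squares at every evaluation and make them part of the model, so
#'   evolution searches only for the response shape. The affine map is
#'   expressible by the gene constants themselves; fitting it directly is
#'   a standard symbolic-regression acceleration.
#' @param restart_after restart the whole population from scratch after
#'   this many generations without the current phase improving its own
#'   best; the best-ever individual is tracked outside the population and
#'   never lost, so the run behaves like an automatic multi-start.
#' @param stall_generations stop early after this many generations without
#'   an RRSE improvement greater than \code{stall_tol}.
#' @param stall_tol minimum RRSE improvement that resets the stall counter.
#' @return A list of class \code{"gep_config"}.
#' @export
gep_config <- function(population_size = 50, head_length = 10, n_genes = 4,
                       generations = 2000, mutation = 0.044,
                       inversion = 0.1, one_point = 0.1, two_point = 0.3,
                       gene_recomb = 0.1, gene_transposition = 0.1,
                       constant_range = c(-10, 10), constant_prob = 0.15,
                       elitism_count = 1, immigrants = 2,
                       polish_constants = 2, linear_scaling = TRUE,
                       restart_after = 120, stall_generations = 500,
                       stall_tol = 1e-6) {
  rates <- c(mutation, inversion, one_point, two_point, gene_recomb,
             gene_transposition)
  stopifnot(all(rates >= 0 & rates <= 1), population_size >= 2,
            head_length >= 1, n_genes >= 1, elitism_count >= 0)
  cfg <- list(
    population_size = population_size, head_length = head_length,
    n_genes = n_genes, generations = generations, mutation = mutation,
    inversion = inversion, one_point = one_point, two_point = two_point,
    gene_recomb = gene_recomb, gene_transposition = gene_transposition,
    constant_range = constant_range, constant_prob = constant_prob,
    elitism_count = elitism_count, immigrants = immigrants,
    polish_constants = polish_constants, linear_scaling = linear_scaling,
    restart_after = restart_after,
    stall_generations = stall_generations, stall_tol = stall_tol,
    tail_length = head_length + 1L,       # h*(amax-1) + 1 with amax = 2
    gene_length = 2L * head_length + 1L
  )
  class(cfg) <- "gep_config"
  cfg
}

random_terminal <- function(n, cfg) {
  codes <- ifelse(runif(n) < cfg$constant_prob, GEP_CONST,
                  GEP_VAR0 + sample.int(9L, n, replace = TRUE))
  consts <- ifelse(codes == GEP_CONST,
                   runif(n, cfg$constant_range[1], cfg$constant_range[2]), 0)
  list(codes = as.integer(codes), consts = consts)
}

random_head_symbol <- function(n, cfg, p_function = 0.5) {
  is_fun <- runif(n) < p_function
  term <- random_terminal(n, cfg)
  codes <- ifelse(is_fun, sample.int(9L, n, replace = TRUE), term$codes)
  consts <- ifelse(is_fun, 0, term$consts)
  list(codes = as.integer(codes), consts = consts)
}

#' Generate a random legal chromosome
#'
#' Head positions hold functions or terminals; tail positions hold only
#' terminals (inputs or constants), so any chromosome decodes without
#' error.
#'
#' @param cfg a \code{\link{gep_config}}.
#' @return An object of class \code{"gep_chromosome"}: integer code matrix
#'   and parallel constant matrix, both (gene length) x (number of genes).
#' @export
random_chromosome <- function(cfg) {
  gl <- cfg$gene_length; h <- cfg$head_length; ng <- cfg$n_genes
  codes <- matrix(0L, gl, ng)
  consts <- matrix(0, gl, ng)
  hd <- random_head_symbol(h * ng, cfg)
  tl <- random_terminal(cfg$tail_length * ng, cfg)
  codes[seq_len(h), ] <- hd$codes
  consts[seq_len(h), ] <- hd$consts
  codes[(h + 1):gl, ] <- tl$codes
  consts[(h + 1):gl, ] <- tl$consts
  structure(list(codes = codes, consts = consts), class = "gep_chromosome")
}

#' Check chromosome legality
#'
#' A chromosome is legal when every tail position holds a terminal and all
#' symbol codes are known.
#' @param chrom a \code{"gep_chromosome"}.
#' @param cfg the matching \code{\link{gep_config}}.
#' @return TRUE or FALSE.
#' @export
is_legal_chromosome <- function(chrom, cfg) {
  codes <- chrom$codes
  if (!all(dim(codes) == c(cfg$gene_length, cfg$n_genes))) return(FALSE)
  if (!all(codes %in% c(1:9, GEP_VAR0 + 1:9, GEP_CONST))) return(FALSE)
  tail_rows <- (cfg$head_length + 1):cfg$gene_length
  all(codes[tail_rows, ] >= GEP_VAR0)
}

#' Decode a chromosome into expression trees
#'
#' Each gene is read breadth-first (Karva order): the expressed region
#' starts at position 1 and extends until every function has received its
#' arguments; unused tail symbols are ignored. Sub-trees are linked by
#' addition.
#'
#' @param chrom a \code{"gep_chromosome"}.
#' @param cfg the matching \code{\link{gep_config}}.
#' @return A list of gene trees; each node is
#'   \code{list(code, const, kids)}.
#' @export
decode_chromosome <- function(chrom, cfg) {
  lapply(seq_len(cfg$n_genes), function(g) {
    codes <- chrom$codes[, g]
    consts <- chrom$consts[, g]
    required <- 1L
    i <- 1L
    while (i <= required) {
      if (i > length(codes))
        stop("illegal gene ", g, ": expression extends past position ",
             length(codes))
      a <- gep_arity(codes[i])
      if (a > 0 && i > cfg$head_length)
        stop("illegal gene ", g, ": function symbol in tail position ", i)
      required <- required + a
      i <- i + 1L
    }
    kids1 <- integer(required); kids2 <- integer(required)
    nxt <- 2L
    for (j in seq_len(required)) {
      a <- gep_arity(codes[j])
      kids1[j] <- if (a >= 1) nxt else 0L
      kids2[j] <- if (a == 2) nxt + 1L else 0L
      nxt <- nxt + a
    }
    build <- function(j) {
      node <- list(code = codes[j], const = consts[j], kids = list())
      if (kids1[j] > 0) node$kids[[1]] <- build(kids1[j])
      if (kids2[j] > 0) node$kids[[2]] <- build(kids2[j])
      node
    }
    build(1L)
  })
}

# protected scalar/vector primitives (shared with the transcribed-equation
# evaluator); semantics match src/gep_eval.cpp
gep_clamp <- function(v) {
  v[is.nan(v)] <- GEP_CLAMP
  pmin(pmax(v, -GEP_CLAMP), GEP_CLAMP)
}
gep_div <- function(a, b) {
  r <- a / b
  r[rep_len(b == 0, length(r))] <- 1
  gep_clamp(r)
}
gep_pow <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  neg <- a < 0 & b != floor(b)
  a[neg] <- -a[neg]
  gep_clamp(a^b)
}

# reference evaluator: naive recursion over the decoded tree (oracle for
# the compiled evaluator)
eval_tree_r <- function(tree, X) {
  ev <- function(node) {
    code <- node$code
    if (code > GEP_VAR0 && code < GEP_CONST) return(X[, code - GEP_VAR0])
    if (code == GEP_CONST) return(rep(node$const, nrow(X)))
    a <- ev(node$kids[[1]])
    if (code == 5) return(gep_clamp(sin(a)))
    if (code == 6) return(gep_clamp(cos(a)))
    if (code == 7) return(gep_clamp(a * a))
    if (code == 8) return(gep_clamp(a * a * a))
    b <- ev(node$kids[[2]])
    switch(as.character(code),
           "1" = gep_clamp(a + b), "2" = gep_clamp(a - b),
           "3" = gep_clamp(a * b), "4" = gep_div(a, b),
           "9" = gep_pow(a, b))
  }
  ev(tree)
}

eval_chromosome_r <- function(chrom, X, cfg) {
  trees <- decode_chromosome(chrom, cfg)
  out <- rep(0, nrow(X))
  for (tr in trees) out <- gep_clamp(out + eval_tree_r(tr, X))
  out
}

as_input_matrix <- function(newdata) {
  if (is.data.frame(newdata)) {
    cols <- paste0("X", 1:9)
    if (!all(cols %in% names(newdata)))
      stop("newdata must contain columns X1..X9")
    newdata <- as.matrix(newdata[, cols])
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  stopifnot(ncol(newdata) == 9)
  storage.mode(newdata) <- "double"
  newdata
}

#' Evaluate a chromosome on input rows
#'
#' Protected evaluation: division by zero yields 1, a negative base with a
#' non-integer exponent uses the absolute base, and every intermediate is
#' clamped to +/- 1e10 (so evaluation is total on any finite input).
#'
#' @param chrom a \code{"gep_chromosome"}.
#' @param newdata matrix or data frame with columns X1..X9.
#' @param cfg the matching \code{\link{gep_config}}.
#' @return Numeric vector of predictions.
#' @export
eval_chromosome <- function(chrom, newdata, cfg) {
  X <- as_input_matrix(newdata)
  gep_eval_cpp(chrom$codes, chrom$consts, X)
}

#' Root relative squared error
#'
#' sqrt(sum((y - yhat)^2) / sum((y - mean(y))^2)): 0 for a perfect model,
#' 1 for the constant mean predictor.
#'
#' @param predictions,observations equal-length numeric vectors (n >= 2).
#' @return Non-negative scalar.
#' @export
rrse <- function(predictions, observations) {
  stopifnot(length(predictions) == length(observations),
            length(observations) >= 2)
  denom <- sum((observations - mean(observations))^2)
  if (denom == 0) stop("observations are constant; RRSE undefined")
  sqrt(sum((observations - predictions)^2) / denom)
}

# ---- genetic operators (all preserve head/tail legality) ----

mutate_chromosome <- function(chrom, cfg) {
  gl <- cfg$gene_length; h <- cfg$head_length; ng <- cfg$n_genes
  hit <- which(matrix(runif(gl * ng) < cfg$mutation, gl, ng), arr.ind = TRUE)
  if (nrow(hit) == 0) return(chrom)
  for (k in seq_len(nrow(hit))) {
    i <- hit[k, 1]; g <- hit[k, 2]
    if (chrom$codes[i, g] == GEP_CONST && runif(1) < 0.5) {
      # multi-scale constant perturbation: coarse moves escape poor values,
      # fine moves polish good ones
      scale <- sample(c(1, 0.1, 0.01), 1)
      chrom$consts[i, g] <- chrom$consts[i, g] + rnorm(1, 0, scale)
    } else if (i <= h) {
      s <- random_head_symbol(1, cfg)
      chrom$codes[i, g] <- s$codes; chrom$consts[i, g] <- s$consts
    } else {
      s <- random_terminal(1, cfg)
      chrom$codes[i, g] <- s$codes; chrom$consts[i, g] <- s$consts
    }
  }
  chrom
}

invert_chromosome <- function(chrom, cfg) {
  if (runif(1) >= cfg$inversion) return(chrom)
  g <- sample.int(cfg$n_genes, 1)
  if (cfg$head_length < 2) return(chrom)
  pts <- sort(sample.int(cfg$head_length, 2))
  seg <- pts[1]:pts[2]
  chrom$codes[seg, g] <- rev(chrom$codes[seg, g])
  chrom$consts[seg, g] <- rev(chrom$consts[seg, g])
  chrom
}

transpose_gene <- function(chrom, cfg) {
  if (cfg$n_genes < 2 || runif(1) >= cfg$gene_transposition) return(chrom)
  gs <- sample.int(cfg$n_genes, 2)
  chrom$codes[, gs[1]] <- chrom$codes[, gs[2]]
  chrom$consts[, gs[1]] <- chrom$consts[, gs[2]]
  chrom
}

# recombination operators act on a pair; positions are aligned so head/tail
# structure is preserved automatically
recombine_pair <- function(c1, c2, cfg, kind) {
  total <- cfg$gene_length * cfg$n_genes
  swap_span <- function(a, b, span) {
    tmpc <- a$codes[span]; tmpk <- a$consts[span]
    a$codes[span] <- b$codes[span]; a$consts[span] <- b$consts[span]
    b$codes[span] <- tmpc; b$consts[span] <- tmpk
    list(a, b)
  }
  if (kind == "one_point") {
    p <- sample.int(total - 1L, 1)
    return(swap_span(c1, c2, (p + 1L):total))
  }
  if (kind == "two_point") {
    p <- sort(sample.int(total, 2))
    return(swap_span(c1, c2, p[1]:p[2]))
  }
  g <- sample.int(cfg$n_genes, 1)
  span <- ((g - 1L) * cfg$gene_length + 1L):(g * cfg$gene_length)
  swap_span(c1, c2, span)
}

#' Evolve a GEP model
#'
#' Initializes a random legal population, then per generation: decodes and
#' scores every chromosome (fitness = 1000 / (1 + RRSE) on the training
#' targets), copies the elite unchanged, fills the rest by
#' fitness-proportional roulette selection, and applies mutation,
#' inversion, gene transposition and one-point/two-point/gene
#' recombination at the configured rates. The best-ever individual is
#' tracked and returned; with at least one elite the best training RRSE is
#' non-increasing across generations. Stops early when the best RRSE has
#' not improved by more than \code{stall_tol} for \code{stall_generations}
#' generations.
#'
#' @param newdata training inputs: matrix or data frame with columns
#'   X1..X9 (normalize beforehand if desired; the packaged pipeline trains
#'   on unit-box inputs and raw-scale targets).
#' @param y training targets (non-constant, length >= 10).
#' @param cfg a \code{\link{gep_config}}.
#' @param seed RNG seed; the same (data, cfg, seed) gives an identical
#'   model.
#' @param trace if TRUE, store the best-RRSE trajectory.
#' @return An object of class \code{"gep_model"}: the best chromosome, its
#'   training RRSE, the infix formula, the config, and (optionally) the
#'   per-generation best-RRSE trace.
#' @export
evolve_gep <- function(newdata, y, cfg = gep_config(), seed = NULL,
                       trace = FALSE) {
  X <- as_input_matrix(newdata)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 10) stop("need at least 10 training rows")
  if (var(y) == 0) stop("training targets are constant")
  with_seed(seed, {
    pop <- replicate(cfg$population_size, random_chromosome(cfg),
                     simplify = FALSE)
    best <- NULL; best_rrse <- Inf
    best_scale <- 1; best_offset <- 0
    last_improve <- 0L
    phase_best <- Inf; last_event <- 0L
    tr <- if (trace) numeric(cfg$generations) else NULL
    for (gen in seq_len(cfg$generations)) {
      scored <- lapply(pop, function(ch)
        score_chromosome(ch, X, y, cfg$linear_scaling))
      errs <- vapply(scored, `[[`, numeric(1), "err")
      gen_best <- which.min(errs)
      if (cfg$polish_constants > 0) {
        # Lamarckian constant refinement of the generation best: jitter its
        # numeric constants at mixed scales and keep any improvement
        ch <- pop[[gen_best]]
        is_const <- ch$codes == GEP_CONST
        if (any(is_const)) {
          for (pp in seq_len(cfg$polish_constants)) {
            cand <- ch
            jit <- rnorm(sum(is_const), 0, sample(c(0.3, 0.03, 0.003), 1))
            cand$consts[is_const] <- cand$consts[is_const] + jit
            sc <- score_chromosome(cand, X, y, cfg$linear_scaling)
            if (sc$err < errs[gen_best]) {
              ch <- cand
              errs[gen_best] <- sc$err
              scored[[gen_best]] <- sc
            }
          }
          pop[[gen_best]] <- ch
        }
      }
      if (errs[gen_best] < best_rrse - cfg$stall_tol) last_improve <- gen
      if (errs[gen_best] < best_rrse) {
        best_rrse <- errs[gen_best]
        best <- pop[[gen_best]]
        best_scale <- scored[[gen_best]]$a
        best_offset <- scored[[gen_best]]$b
      }
      if (trace) tr[gen] <- best_rrse
      if (best_rrse <= 1e-9 ||
          gen - last_improve >= cfg$stall_generations) {
        if (trace) tr <- tr[seq_len(gen)]
        break
      }
      if (gen == cfg$generations) break
      # phase clock: a phase that stops improving its own best (not just
      # the global best) is abandoned and the whole population restarted;
      # the global best-ever is tracked outside the population, so
      # restarts are free lunches for the returned model
      if (errs[gen_best] < phase_best - 1e-4) {
        phase_best <- errs[gen_best]
        last_event <- gen
      }
      if (!is.null(cfg$restart_after) &&
          cfg$elitism_count < cfg$population_size &&
          gen - last_event >= cfg$restart_after) {
        pop <- replicate(cfg$population_size, random_chromosome(cfg),
                         simplify = FALSE)
        phase_best <- Inf
        last_event <- gen
        next
      }
      fitness <- 1000 / (1 + errs)
      ord <- order(fitness, decreasing = TRUE)
      n_elite <- min(cfg$elitism_count, cfg$population_size)
      elites <- pop[ord[seq_len(n_elite)]]
      n_off <- cfg$population_size - n_elite
      nextpop <- elites
      if (n_off > 0) {
        parents <- sample.int(cfg$population_size, n_off, replace = TRUE,
                              prob = fitness)
        off <- pop[parents]
        off <- lapply(off, mutate_chromosome, cfg = cfg)
        off <- lapply(off, invert_chromosome, cfg = cfg)
        off <- lapply(off, transpose_gene, cfg = cfg)
        # random immigrants: continuous source of fresh genetic material
        if (cfg$immigrants > 0 && n_off > cfg$immigrants) {
          for (im in seq_len(cfg$immigrants))
            off[[n_off - im + 1]] <- random_chromosome(cfg)
        }
        if (n_off >= 2) {
          for (kind in c("one_point", "two_point", "gene_recomb")) {
            rate <- switch(kind, one_point = cfg$one_point,
                           two_point = cfg$two_point, cfg$gene_recomb)
            for (p in seq(1, n_off - 1, by = 2)) {
              if (runif(1) < rate) {
                res <- recombine_pair(off[[p]], off[[p + 1]], cfg, kind)
                off[[p]] <- res[[1]]; off[[p + 1]] <- res[[2]]
              }
            }
          }
        }
        nextpop <- c(nextpop, off)
      }
      pop <- nextpop
    }
    model <- structure(list(chromosome = best, rrse = best_rrse,
                            scale = best_scale, offset = best_offset,
                            config = cfg, trace = tr),
                       class = "gep_model")
    model$formula <- to_formula(model)
    model
  })
}

# per-individual score: protected tree outputs, optionally mapped through
# the least-squares-optimal affine transform before RRSE
score_chromosome <- function(ch, X, y, linear_scaling) {
  t <- gep_eval_cpp(ch$codes, ch$consts, X)
  if (!linear_scaling) return(list(err = rrse(t, y), a = 1, b = 0))
  vt <- var(t)
  if (!is.finite(vt) || vt < 1e-20) {
    a <- 0; b <- mean(y)
  } else {
    a <- cov(t, y) / vt
    b <- mean(y) - a * mean(t)
  }
  list(err = rrse(a * t + b, y), a = a, b = b)
}

#' @export
predict.gep_model <- function(object, newdata, ...) {
  object$scale * eval_chromosome(object$chromosome, newdata,
                                 object$config) + object$offset
}

#' @export
print.gep_model <- function(x, ...) {
  cat("GEP model (", x$config$n_genes, "genes, head",
      x$config$head_length, ")\n")
  cat("training RRSE:", format(x$rrse, digits = 4), "\n")
  cat(x$formula, "\n")
  invisible(x)
}

format_tree <- function(node, digits = 15) {
  code <- node$code
  if (code > GEP_VAR0 && code < GEP_CONST)
    return(paste0("X", code - GEP_VAR0))
  if (code == GEP_CONST)
    return(format(node$const, digits = digits, trim = TRUE,
                  scientific = FALSE))
  nm <- GEP_FUNCTIONS$name[code]
  a <- format_tree(node$kids[[1]], digits)
  if (nm == "sin") return(paste0("sin(", a, ")"))
  if (nm == "cos") return(paste0("cos(", a, ")"))
  if (nm == "sq") return(paste0("(", a, ")^2"))
  if (nm == "cu") return(paste0("(", a, ")^3"))
  b <- format_tree(node$kids[[2]], digits)
  if (nm == "pow") return(paste0("(", a, ")^(", b, ")"))
  paste0("(", a, " ", nm, " ", b, ")")
}

#' Render a chromosome or model as an infix formula
#'
#' The four gene sub-expressions are printed as bracketed terms joined by
#' \code{+}, mirroring the layout of the packaged equation registry.
#' Parsing the result with \code{\link{gep_parse_formula}} recovers a
#' function with identical protected semantics.
#'
#' @param x a \code{"gep_chromosome"} or \code{"gep_model"}.
#' @param cfg the matching \code{\link{gep_config}} (taken from the model
#'   when \code{x} is a model).
#' @return A single string.
#' @export
to_formula <- function(x, cfg = NULL) {
  scale <- 1; offset <- 0
  if (inherits(x, "gep_model")) {
    cfg <- x$config
    scale <- x$scale; offset <- x$offset
    x <- x$chromosome
  }
  stopifnot(!is.null(cfg))
  trees <- decode_chromosome(x, cfg)
  terms <- vapply(trees, format_tree, character(1))
  body <- paste0("[", terms, "]", collapse = " + ")
  if (identical(scale, 1) && identical(offset, 0)) return(body)
  paste0(format(offset, digits = 15, trim = TRUE, scientific = FALSE),
         " + ", format(scale, digits = 15, trim = TRUE, scientific = FALSE),
         " * (", body, ")")
}

#' Parse an infix formula into an evaluable surface
#'
#' Accepts the bracketed-sum syntax emitted by \code{\link{to_formula}}
#' (and the packaged equation registry): operators + - * / ^ and functions
#' sin, cos over X1..X9 and numeric constants. Division and power are
#' protected and every term is clamped exactly as in chromosome
#' evaluation.
#'
#' @param text formula string.
#' @return A function of a matrix/data frame with columns X1..X9 returning
#'   predictions.
#' @export
gep_parse_formula <- function(text) {
  text <- gsub("\\[", "(", gsub("\\]", ")", text))
  expr <- parse(text = text)[[1]]
  force(expr)
  function(newdata) {
    X <- as_input_matrix(newdata)
    env <- new.env(parent = baseenv())
    for (i in 1:9) assign(paste0("X", i), X[, i], envir = env)
    assign("/", function(a, b) gep_div(a, b), envir = env)
    assign("^", function(a, b) gep_pow(a, b), envir = env)
    assign("+", function(a, b) gep_clamp(a + b), envir = env)
    assign("-", function(a, b = NULL) {
      if (is.null(b)) gep_clamp(-a) else gep_clamp(a - b)
    }, envir = env)
    assign("*", function(a, b) gep_clamp(a * b), envir = env)
    assign("sin", function(a) gep_clamp(sin(a)), envir = env)
    assign("cos", function(a) gep_clamp(cos(a)), envir = env)
    assign("(", function(a) a, envir = env)
    gep_clamp(eval(expr, env))
  }
}

#' Serialize a GEP model to JSON
#' @param model a \code{"gep_model"}.
#' @param path output file path.
#' @export
write_gep_model <- function(model, path) {
  jsonlite::write_json(list(
    type = "gep",
    config = unclass(model$config),
    codes = model$chromosome$codes,
    consts = model$chromosome$consts,
    scale = model$scale,
    offset = model$offset,
    rrse = model$rrse,
    formula = model$formula
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
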