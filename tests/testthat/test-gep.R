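test_that("Karva decoding expresses (a+b)*(c-d) from its linear gene", {
  cfg <- gep_config(head_length = 3, n_genes = 1)
  ch <- chrom_from_symbols(list(c("*", "+", "-", "X1", "X2", "X3", "X4")),
                           cfg)
  X <- matrix(c(1, 2, 4, 3, rep(0, 5)), 1, 9)
  expect_equal(eval_chromosome(ch, X, cfg), (1 + 2) * (4 - 3))
  expect_equal(to_formula(ch, cfg), "[((X1 + X2) * (X3 - X4))]")
})

test_that("a terminal at the gene root decodes to a single leaf", {
  cfg <- gep_config(head_length = 3, n_genes = 1)
  ch <- chrom_from_symbols(list(c("X3")), cfg)
  expect_equal(to_formula(ch, cfg), "[X3]")
  X <- random_input_matrix(4, seed = 1)
  expect_equal(eval_chromosome(ch, X, cfg), X[, 3])
})

test_that("protected evaluation is total and finite", {
  cfg <- gep_config(head_length = 2, n_genes = 1)
  # X1 / X2 with X2 = 0 -> protected to 1
  ch <- chrom_from_symbols(list(c("/", "X1", "X2")), cfg)
  X <- matrix(c(5, 0, rep(0, 7)), 1, 9)
  expect_equal(eval_chromosome(ch, X, cfg), 1)
  # power of a negative base with fractional exponent stays real
  ch2 <- chrom_from_symbols(list(c("pow", "X1", "X2")), cfg)
  X2 <- matrix(c(-8, 0.5, rep(0, 7)), 1, 9)
  expect_equal(eval_chromosome(ch2, X2, cfg), sqrt(8))
  # overflow clamps rather than propagating Inf
  ch3 <- chrom_from_symbols(list(c("pow", "1e9", "1e9")), cfg)
  v <- eval_chromosome(ch3, random_input_matrix(3, seed = 2), cfg)
  expect_true(all(is.finite(v)) && all(abs(v) <= 1e10))
})

test_that("compiled evaluator agrees with the naive recursive evaluator", {
  cfg <- gep_config()
  set.seed(99)
  for (i in 1:100) {
    ch <- random_chromosome(cfg)
    X <- random_input_matrix(10)
    expect_equal(eval_chromosome(ch, X, cfg),
                 walnutmedia:::eval_chromosome_r(ch, X, cfg),
                 tolerance = 1e-12)
  }
})

test_that("rrse matches hand computations and its fixed points", {
  expect_equal(rrse(c(1, 2, 3), c(1, 2, 3)), 0)
  y <- c(2, 4, 9)
  expect_equal(rrse(rep(mean(y), 3), y), 1)
  expect_equal(rrse(c(1, 1, 3), c(1, 2, 3)), sqrt(1 / 2))
  expect_error(rrse(c(1, 2), c(5, 5)))
})

test_that("genetic operators preserve chromosome legality", {
  cfg <- gep_config()
  set.seed(7)
  n_checks <- 0
  for (i in 1:2000) {
    a <- random_chromosome(cfg)
    b <- random_chromosome(cfg)
    expect_true(is_legal_chromosome(walnutmedia:::mutate_chromosome(a, cfg), cfg))
    expect_true(is_legal_chromosome(walnutmedia:::invert_chromosome(a, cfg), cfg))
    expect_true(is_legal_chromosome(walnutmedia:::transpose_gene(a, cfg), cfg))
    for (kind in c("one_point", "two_point", "gene_recomb")) {
      res <- walnutmedia:::recombine_pair(a, b, cfg, kind)
      expect_true(is_legal_chromosome(res[[1]], cfg))
      expect_true(is_legal_chromosome(res[[2]], cfg))
    }
    n_checks <- n_checks + 5
  }
  expect_gte(n_checks, 10000)
})

test_that("evolution is reproducible and monotone under elitism", {
  bm <- make_benchmark("planted_linear", n_sample = 32, seed = 2)
  X <- bm$data[paste0("X", 1:9)]; y <- bm$data$y
  cfg <- gep_config(generations = 40, stall_generations = 40)
  m1 <- evolve_gep(X, y, cfg, seed = 5, trace = TRUE)
  m2 <- evolve_gep(X, y, cfg, seed = 5)
  expect_identical(m1$formula, m2$formula)
  expect_true(all(diff(m1$trace) <= 0))
})

test_that("degenerate configurations behave as contracts promise", {
  bm <- make_benchmark("planted_linear", n_sample = 16, seed = 4)
  X <- bm$data[paste0("X", 1:9)]; y <- bm$data$y
  # full elitism freezes the population after generation 1
  cfg <- gep_config(population_size = 10, elitism_count = 10,
                    generations = 30, stall_generations = 30,
                    immigrants = 0, polish_constants = 0)
  m <- evolve_gep(X, y, cfg, seed = 1, trace = TRUE)
  expect_true(all(m$trace == m$trace[1]))
  # all operator rates zero: the final best equals the initial best
  cfg0 <- gep_config(mutation = 0, inversion = 0, one_point = 0,
                     two_point = 0, gene_recomb = 0,
                     gene_transposition = 0, immigrants = 0,
                     polish_constants = 0, restart_after = NULL,
                     generations = 25, stall_generations = 25)
  m0 <- evolve_gep(X, y, cfg0, seed = 2, trace = TRUE)
  expect_equal(m0$rrse, m0$trace[1])
  expect_error(evolve_gep(X[1:5, ], y[1:5], cfg0, seed = 1), "10")
  expect_error(evolve_gep(X, rep(1, nrow(X)), cfg0, seed = 1), "constant")
})

test_that("formulas round-trip through the printer/parser pair", {
  cfg <- gep_config()
  set.seed(21)
  for (i in 1:10) {
    ch <- random_chromosome(cfg)
    f <- gep_parse_formula(to_formula(ch, cfg))
    X <- random_input_matrix(5)
    expect_equal(f(X), eval_chromosome(ch, X, cfg), tolerance = 1e-8)
  }
})

test_that("gep models serialize to JSON with their formula", {
  bm <- make_benchmark("planted_linear", n_sample = 16, seed = 4)
  m <- evolve_gep(bm$data[paste0("X", 1:9)], bm$data$y,
                  gep_config(generations = 10, stall_generations = 10),
                  seed = 3)
  f <- tempfile(fileext = ".json")
  write_gep_model(m, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$type, "gep")
  expect_equal(back$rrse, m$rrse)
  expect_equal(back$formula, m$formula)
})
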