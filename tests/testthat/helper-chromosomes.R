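# build a chromosome by hand from symbol names, padding the tail with X1
chrom_from_symbols <- function(symbols, cfg, consts = NULL) {
  code_of <- function(s) {
    if (s %in% GEP_FUNCTIONS_TEST$name)
      return(GEP_FUNCTIONS_TEST$code[GEP_FUNCTIONS_TEST$name == s])
    if (grepl("^X[1-9]$", s)) return(10L + as.integer(sub("X", "", s)))
    20L  # constant
  }
  gl <- cfg$gene_length
  codes <- matrix(11L, gl, cfg$n_genes)  # X1 filler
  cvals <- matrix(0, gl, cfg$n_genes)
  for (g in seq_along(symbols)) {
    syms <- symbols[[g]]
    for (i in seq_along(syms)) {
      codes[i, g] <- code_of(syms[i])
      if (codes[i, g] == 20L)
        cvals[i, g] <- if (is.null(consts)) as.numeric(syms[i]) else
          consts[[g]][i]
    }
  }
  structure(list(codes = codes, consts = cvals), class = "gep_chromosome")
}

GEP_FUNCTIONS_TEST <- data.frame(
  code = 1:9,
  name = c("+", "-", "*", "/", "sin", "cos", "sq", "cu", "pow"),
  stringsAsFactors = FALSE
)

random_input_matrix <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(runif(n * 9), n, 9)
  colnames(X) <- paste0("X", 1:9)
  X
}
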