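#!/usr/bin/env Rscript

# Stage 3: cross-validated model comparison per genotype (tenfold-CV
# training statistics plus held-out test statistics for MLR, KNN, MLPNN
# and GEP on all four responses) and the qualitative ordering of the
# nonlinear learners against linear regression.
#
# Writes: results/comparison_<genotype>.csv

library(walnutmedia)

seed <- 1
dir.create("results", showWarnings = FALSE)

for (g in c("Chandler", "Rayen")) {
  rep_file <- file.path("results", paste0("replicates_", g, ".csv"))
  data <- if (file.exists(rep_file)) read_replicates_csv(rep_file) else NULL
  cmp <- suppressWarnings(comparison_report(g, data = data, seed = seed))
  write.csv(cmp, file.path("results", paste0("comparison_", g, ".csv")),
            row.names = FALSE)
  cat("\n", g, "test-set R2 by model and response:\n")
  wide <- reshape(cmp[c("model", "response", "test_r2")],
                  idvar = "response", timevar = "model", direction = "wide")
  print(wide, digits = 3, row.names = FALSE)
  for (r in c("PR", "CW", "STN", "Vit")) {
    sub <- cmp[cmp$response == r, ]
    beats <- sub$test_r2[sub$model != "MLR"] >
      sub$test_r2[sub$model == "MLR"]
    cat(sprintf("  %s: nonlinear models beating MLR: %d/3\n", r, sum(beats)))
  }
}
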