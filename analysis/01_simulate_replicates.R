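#!/usr/bin/env Rscript

# Stage 1: expand the published per-treatment summaries (mean +/- SE over
# 8 jars) into replicate-level datasets for both genotypes, and fix the
# 70/30 train/test split used by every later stage.
#
# Writes: results/replicates_<genotype>.csv, results/split_<genotype>.json

library(walnutmedia)

seed <- 1
dir.create("results", showWarnings = FALSE)

for (g in c("Chandler", "Rayen")) {
  design <- packaged_design(g)
  reps <- expand_replicates(design, n_reps = 8, seed = seed)
  write_replicates_csv(reps, file.path("results",
                                       paste0("replicates_", g, ".csv")))
  sp <- split_train_test(reps, seed = seed + 1)
  jsonlite::write_json(
    list(seed = seed + 1, train_idx = attr(sp, "train_idx"),
         n_train = nrow(sp$train), n_test = nrow(sp$test)),
    file.path("results", paste0("split_", g, ".json")), auto_unbox = TRUE)
  cat(sprintf(
    "%s: %d replicate records (%d treatments x 8 jars); split %d train / %d test\n",
    g, nrow(reps), nrow(design), nrow(sp$train), nrow(sp$test)))
  # moment fidelity spot check
  dkw <- reps$PR[reps$treatment_id == "DKW"]
  cat(sprintf("  DKW control PR: mean %.4f (published %.2f), SE %.4f (published %.2f)\n",
              mean(dkw), design$PR_mean[design$treatment_id == "DKW"],
              sd(dkw) / sqrt(8), design$PR_se[design$treatment_id == "DKW"]))
}
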