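#!/usr/bin/env Rscript

# Stage 2: fit the four response-surface families (MLR, KNN, MLPNN, GEP)
# per genotype and response on the training split, and export the final
# models plus observed-vs-predicted plotting data.
#
# Reads:  results/replicates_<genotype>.csv, results/split_<genotype>.json
# Writes: results/models/<genotype>_<response>_<model>.json,
#         results/obs_vs_pred/<genotype>_<response>_<model>.csv

library(walnutmedia)

seed <- 1
dir.create("results/models", showWarnings = FALSE, recursive = TRUE)
dir.create("results/obs_vs_pred", showWarnings = FALSE, recursive = TRUE)

for (g in c("Chandler", "Rayen")) {
  rep_file <- file.path("results", paste0("replicates_", g, ".csv"))
  if (!file.exists(rep_file))
    stop("missing ", rep_file, "; run analysis/01_simulate_replicates.R first")
  reps <- read_replicates_csv(rep_file)
  sp_meta <- jsonlite::read_json(file.path("results",
                                           paste0("split_", g, ".json")),
                                 simplifyVector = TRUE)
  train <- reps[sp_meta$train_idx, ]
  Xraw <- as.matrix(train[paste0("X", 1:9)])
  Xn <- suppressWarnings(normalize_factors(Xraw, clamp = TRUE))
  folds <- make_cv_folds(nrow(train), k = 10, seed = seed + 2)

  for (r in c("PR", "CW", "STN", "Vit")) {
    y <- train[[r]]
    models <- list(
      MLR = fit_mlr(Xraw, y),
      KNN = select_knn(Xn, y, folds),
      MLPNN = fit_mlpnn(Xn, y, H = 15, activation = "tanh",
                        seed = seed + 3, restarts = 2, maxit = 150),
      GEP = evolve_gep(Xn, y, gep_config(generations = 400,
                                         stall_generations = 400),
                       seed = seed + 4)
    )
    for (nm in names(models)) {
      path <- file.path("results/models",
                        sprintf("%s_%s_%s.json", g, r, nm))
      if (nm == "GEP") write_gep_model(models[[nm]], path)
      else write_baseline_model(models[[nm]], path)
      ex <- export_obs_vs_pred(models[[nm]], reps, r,
                               normalize_inputs = nm != "MLR")
      exf <- file.path("results/obs_vs_pred",
                       sprintf("%s_%s_%s.csv", g, r, nm))
      write.csv(data.frame(ex, slope = attr(ex, "slope"),
                           intercept = attr(ex, "intercept"),
                           r2 = attr(ex, "r2")), exf, row.names = FALSE)
    }
    cat(sprintf("%s %s: GEP training RRSE %.3f | %s\n", g, r,
                models$GEP$rrse,
                substr(models$GEP$formula, 1, 60)))
  }
}
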