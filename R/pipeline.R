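# End-to-end orchestration: generate replicate data, fit and evaluate all
# models, optimize the medium, and write every artifact under one output
# directory. The numbered scripts under analysis/ are thin drivers over
# these functions.

#' Default pipeline configuration
#'
#' One master seed spawns per-stage sub-seeds (via a fixed splitting
#' scheme), so each stage is individually reproducible.
#'
#' @param genotypes genotypes to process.
#' @param seed master seed.
#' @param n_reps replicates per treatment.
#' @param out_dir output directory.
#' @param ... overrides passed to \code{\link{comparison_report}} (model
#'   budgets) and \code{\link{pso_params}} via names \code{pso_iterations}
#'   and \code{pso_swarm}.
#' @return Config list.
#' @export
pipeline_config <- function(genotypes = GENOTYPES, seed = 1, n_reps = 8,
                            out_dir = "results", ...) {
  cfg <- list(genotypes = match.arg(genotypes, GENOTYPES, several.ok = TRUE),
              seed = seed, n_reps = n_reps, out_dir = out_dir,
              extra = list(...))
  stopifnot(is.numeric(seed), n_reps >= 2)
  cfg
}

pipeline_log <- function(...) message("[walnutmedia] ", ...)

#' Run the full reproduction pipeline
#'
#' Per genotype: writes the replicate-level CSV, the train/test split
#' manifest, the model-comparison CSV (four models x four responses),
#' observed-vs-predicted plotting CSVs for the final models, and the
#' optimized-medium recipe CSV (from the transcribed equation surfaces,
#' with the Fk -> Xk substitution applied to the flagged equations). A run
#' manifest records the seed and per-stage sub-seeds.
#'
#' @param config from \code{\link{pipeline_config}}.
#' @return Invisibly, a list of per-genotype artifact paths.
#' @export
run_media_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  extra <- config$extra
  arg <- function(name, default) if (!is.null(extra[[name]])) extra[[name]] else default
  out <- list()
  for (g in config$genotypes) {
    pipeline_log("genotype ", g, ": simulating replicates")
    data <- expand_replicates(packaged_design(g), n_reps = config$n_reps,
                              seed = derive_seed(config$seed, 1))
    rep_path <- file.path(config$out_dir, paste0("replicates_", g, ".csv"))
    write_replicates_csv(data, rep_path)

    split <- split_train_test(data, seed = derive_seed(config$seed, 2))
    split_path <- file.path(config$out_dir, paste0("split_", g, ".json"))
    jsonlite::write_json(list(seed = derive_seed(config$seed, 2),
                              train_idx = attr(split, "train_idx"),
                              n_train = nrow(split$train),
                              n_test = nrow(split$test)),
                         split_path, auto_unbox = TRUE)

    pipeline_log("genotype ", g, ": fitting and evaluating models")
    report <- comparison_report(
      g, data = data, seed = config$seed,
      responses = arg("responses", RESPONSES),
      knn_k_grid = arg("knn_k_grid", 1:15),
      mlp_H_grid = arg("mlp_H_grid", 15),
      mlp_activations = arg("mlp_activations", "tanh"),
      mlp_restarts = arg("mlp_restarts", 2),
      gep_generations = arg("gep_generations", 300),
      gep_final_generations = arg("gep_final_generations", 1200))
    cmp_path <- file.path(config$out_dir, paste0("comparison_", g, ".csv"))
    write.csv(report, cmp_path, row.names = FALSE)

    pipeline_log("genotype ", g, ": optimizing medium over transcribed surfaces")
    surfaces <- get_equations(g, substitute_F = TRUE)
    opt <- optimize_medium(
      surfaces, objective_spec(g),
      params = pso_params(swarm_size = arg("pso_swarm", 50),
                          iterations = arg("pso_iterations", 500),
                          seed = derive_seed(config$seed, 5)))
    recipe_path <- file.path(config$out_dir, paste0("recipe_", g, ".csv"))
    write_recipe_csv(opt, recipe_path)

    manifest <- list(genotype = g, master_seed = config$seed,
                     stage_seeds = list(simulate = derive_seed(config$seed, 1),
                                        split = derive_seed(config$seed, 2),
                                        pso = derive_seed(config$seed, 5)),
                     files = basename(c(rep_path, split_path, cmp_path,
                                        recipe_path)))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir,
                                   paste0("manifest_", g, ".json")),
                         auto_unbox = TRUE)
    out[[g]] <- manifest
  }
  invisible(out)
}
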