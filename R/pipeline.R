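#' Pipeline configuration
#'
#' One list controlling an end-to-end run: simulation parameters, stage
#' toggles, and per-stage settings. `read_pipeline_config()` loads the same
#' structure from a YAML file; unknown fields are rejected.
#'
#' @param sim A [simulation_config()].
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "count", "score", "features", "train", "switch")`.
#' @param floor Enrichment detection floor.
#' @param tau Switch-calling threshold.
#' @param model A [model_config()].
#' @param plddt_coupling Structure-feature coupling passed to
#'   [generate_structure_table()].
#' @param seed Global seed; overrides `sim$seed` and `model$seed`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            stages = c("simulate", "count", "score",
                                       "features", "train", "switch"),
                            floor = -10, tau = 2, model = model_config(),
                            plddt_coupling = 0, seed = NULL) {
  known <- c("simulate", "count", "score", "features", "train", "switch")
  if (!all(stages %in% known)) {
    it_stop(sprintf("unknown stages: %s",
                    paste(setdiff(stages, known), collapse = ", ")),
            "invalid_config")
  }
  if (!is.null(seed)) {
    sim$seed <- seed
    model$seed <- seed
  }
  structure(list(sim = sim, stages = stages, floor = floor, tau = tau,
                 model = model, plddt_coupling = plddt_coupling),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with top-level blocks `sim`, `model`, and scalar
#'   fields `stages`, `floor`, `tau`, `plddt_coupling`, `seed`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    it_stop(sprintf("config file '%s' does not exist", path), "invalid_config")
  }
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  bad <- setdiff(names(sim_args), names(formals(simulation_config)))
  if (length(bad)) {
    it_stop(sprintf("unknown sim fields: %s", paste(bad, collapse = ", ")),
            "invalid_config")
  }
  sim <- do.call(simulation_config, sim_args)
  model <- do.call(model_config, raw$model %||% list())
  pipeline_config(sim = sim,
                  stages = raw$stages %||% c("simulate", "count", "score",
                                             "features", "train", "switch"),
                  floor = raw$floor %||% -10, tau = raw$tau %||% 2,
                  model = model,
                  plddt_coupling = raw$plddt_coupling %||% 0,
                  seed = raw$seed)
}

#' Run the full analysis pipeline on a simulated screen
#'
#' Executes the enabled stages in order — simulate (ground truth, reads,
#' homologs, structure), count (junction calling), score (enrichment +
#' replicate summary), features (conservation, indel and structure features
#' mapped to sites), train (cross-validated gradient boosting with
#' benchmarks and importances), switch (light-vs-dark calling; run only
#' when the simulation plants switch sites) — and writes stage outputs plus
#' a JSON manifest into `out_dir`.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) {
    it_stop("config must be a pipeline_config", "invalid_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("inserttol")),
                   seed = config$sim$seed, stages = list())
  res <- list()
  log_stage <- function(name, outputs) {
    manifest$stages[[name]] <<- list(outputs = outputs)
    message(sprintf("[%s] done", name))
  }
  has_switch <- config$sim$switch_spec$n_switch > 0
  conditions <- if (has_switch) c("dark", "light") else "none"

  if ("simulate" %in% config$stages) {
    truth <- simulate_ground_truth(config$sim)
    sim <- generate_library_reads(truth, config$sim, conditions = conditions,
                                  out_dir = file.path(out_dir, "fastq"))
    hom <- generate_homologs(truth, config$sim$homolog_spec,
                             subseed(config$sim$seed, 41))
    struct <- generate_structure_table(truth, subseed(config$sim$seed, 43),
                                       plddt_coupling = config$plddt_coupling)
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(c(parent = truth$parent_protein)),
      file.path(out_dir, "parent_protein.fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(c(parent_cds = truth$parent_cds,
                                 insert_cds = truth$insert_cds)),
      file.path(out_dir, "cds.fasta"))
    Biostrings::writeXStringSet(hom$sequences,
                                file.path(out_dir, "homologs.fasta"))
    write_structure_tsv(struct, file.path(out_dir, "structure.tsv"))
    jsonlite::write_json(
      truth[c("log2_lambda", "switch_delta", "conservation_weight",
              "insertion_rate", "deletion_rate")],
      file.path(out_dir, "ground_truth.json"), digits = NA)
    res$sim <- sim; res$homologs <- hom; res$structure <- struct
    res$truth <- truth
    log_stage("simulate", c("fastq/", "parent_protein.fasta", "cds.fasta",
                            "homologs.fasta", "structure.tsv",
                            "ground_truth.json"))
  }

  index <- NULL
  if ("count" %in% config$stages) {
    index <- build_junction_index(res$truth$parent_cds, res$truth$insert_cds,
                                  config$sim$junction_k)
    res$counts <- lapply(res$sim$pools, function(p) {
      ct <- count_reads(p$reads, index, replicate_id = p$replicate,
                        condition = p$condition, pool = p$pool)
      f <- file.path(out_dir, sprintf("counts_%s_%s_rep%d.tsv",
                                      p$condition, p$pool, p$replicate))
      write_count_tsv(ct, f)
      ct
    })
    log_stage("count", "counts_*.tsv")
  }

  if ("score" %in% config$stages) {
    res$profiles <- score_simulated_screen(res$sim, index = index,
                                           floor = config$floor)
    for (cond in names(res$profiles)) {
      write_profile_tsv(res$profiles[[cond]],
                        file.path(out_dir, sprintf("scores_%s.tsv", cond)))
    }
    log_stage("score", "scores_*.tsv")
  }

  if ("features" %in% config$stages) {
    aln <- align_homologs(res$truth$parent_protein, res$homologs$sequences)
    msa <- msa_from_alignments(aln)
    stats <- indel_stats(aln)
    rtab <- residue_feature_table(res$truth$parent_protein, msa, stats,
                                  res$structure)
    res$sites <- map_to_sites(rtab, stats)
    write.table(res$sites, file.path(out_dir, "site_features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    prof <- res$profiles[[if (has_switch) "dark" else "none"]]
    res$correlations <- feature_correlations(res$sites, prof)
    write.table(res$correlations,
                file.path(out_dir, "feature_correlations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("features", c("site_features.tsv", "feature_correlations.tsv"))
  }

  if ("train" %in% config$stages) {
    prof <- res$profiles[[if (has_switch) "dark" else "none"]]
    ds <- make_tol_dataset(res$sites, binarize(prof))
    sp <- split_and_scale(ds, config$model)
    res$cv <- cross_validate(sp$train$X, sp$train$y, config$model)
    res$benchmarks <- evaluate_with_benchmarks(res$cv$model, sp$test,
                                               sp$train, config$model)
    res$importance <- importance(res$cv$model, sp$train$X, sp$train$y,
                                 config$model)
    metrics <- list(fold_auroc = res$cv$fold_auroc,
                    mean_auroc = res$cv$mean_auroc,
                    fold_ap = res$cv$fold_ap, mean_ap = res$cv$mean_ap)
    jsonlite::write_json(metrics, file.path(out_dir, "cv_metrics.json"),
                         digits = NA)
    write.table(res$importance, file.path(out_dir, "importance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$benchmarks, file.path(out_dir, "benchmarks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("train", c("cv_metrics.json", "importance.tsv",
                         "benchmarks.tsv"))
  }

  if ("switch" %in% config$stages && has_switch) {
    cmp <- call_switches(compare_conditions(res$profiles$dark,
                                            res$profiles$light),
                         tau = config$tau)
    res$switches <- cmp
    write_comparison_tsv(cmp, file.path(out_dir, "switches.tsv"))
    log_stage("switch", "switches.tsv")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  res$manifest <- manifest
  invisible(res)
}
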