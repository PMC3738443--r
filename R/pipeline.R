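## Single entry point chaining pipeline stages from a YAML config, with a
## run manifest recording seeds, parameters and outputs. Stages execute in
## canonical order: simulate -> qc -> normalize -> associate -> characterize
## -> enrich -> replicate. Stochastic stages refuse to run unseeded.

.stage_order <- c("simulate", "qc", "normalize", "associate", "characterize",
                  "enrich", "replicate")

#' Validate a pipeline run configuration
#'
#' @param config Path to a YAML file or a named list. Top-level fields:
#'   `out_dir`, `stages` (subset of simulate/qc/normalize/associate/
#'   characterize/enrich/replicate), and one parameter block per stage.
#'   Input files referenced by a block (`beta`, `detection`, `manifest`,
#'   `samples`, `annotation`, `gene_sets`, `blacklist`, `validation`) must
#'   exist at validation time. Stochastic stages (`simulate`,
#'   `normalize` with subsetting/nonparametric mode, `associate` with
#'   permutations) must carry a `seed`.
#' @return The validated config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_invalid(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop_invalid("config needs `out_dir`")
  stages <- config$stages %||% c("simulate", "qc", "normalize", "associate",
                                 "characterize")
  bad <- setdiff(stages, .stage_order)
  if (length(bad)) stop_invalid(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  config$stages <- .stage_order[.stage_order %in% stages]
  file_keys <- c("beta", "detection", "manifest", "samples", "annotation",
                 "gene_sets", "blacklist", "validation")
  for (st in config$stages) {
    blk <- config[[st]] %||% list()
    for (key in intersect(names(blk), file_keys)) {
      if (is.character(blk[[key]]) && !file.exists(blk[[key]])) {
        stop_invalid(sprintf("stage '%s': file not found: %s", st, blk[[key]]))
      }
    }
  }
  if ("simulate" %in% config$stages && is.null(config$simulate$seed)) {
    stop_invalid("stage 'simulate' requires a seed")
  }
  if (!"simulate" %in% config$stages) {
    first <- config$stages[1]
    blk <- config[[first]] %||% list()
    if (is.null(blk$beta)) {
      stop_invalid(sprintf("stage '%s' needs a `beta` input when 'simulate' is not run", first))
    }
  }
  config
}

run_stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          class = "methylewas_stage_error", parent = e)
  })
}

#' Run the analysis pipeline from a config
#'
#' Executes the configured stages in canonical order, writing each stage's
#' outputs as TSV under `out_dir` plus a `run_manifest.json` recording the
#' config hash, seeds, package version and output files. Reruns with the
#' same config and seeds produce byte-identical result TSVs.
#'
#' @param config Path to a YAML config or a named list (see
#'   [validate_run_config()]).
#' @return Invisibly, the run manifest list.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(x, name) {
    path <- file.path(config$out_dir, name)
    if (is.matrix(x)) write_beta_matrix(x, path) else write_result_tsv(x, path)
    outputs[[length(outputs) + 1L]] <<- path
    path
  }
  seeds <- list()

  beta <- det <- manifest <- samples <- truth <- NULL
  assoc <- NULL

  for (st in config$stages) {
    blk <- config[[st]] %||% list()
    inform(sprintf("[methylewas] stage: %s", st))
    run_stage(st, switch(
      st,
      simulate = {
        cfg_args <- blk[setdiff(names(blk), character(0))]
        cfg <- do.call(simulation_config, cfg_args)
        seeds$simulate <- cfg$seed
        sim <- simulate_dataset(cfg)
        beta <- sim$beta; det <- sim$detection
        manifest <- sim$manifest; samples <- sim$samples; truth <- sim$truth
        emit(sim$beta, "beta_raw.tsv")
        emit(sim$detection, "detection.tsv")
        emit(sim$manifest, "manifest.tsv")
        emit(sim$samples, "samples.tsv")
        emit(sim$truth$probes, "truth.tsv")
      },
      qc = {
        if (is.null(beta)) {
          beta <- read_beta_matrix(blk$beta)
          det <- read_detection_matrix(blk$detection)
          manifest <- read_manifest(blk$manifest)
          samples <- read_sample_sheet(blk$samples)
        }
        if (!is.null(blk$blacklist)) {
          manifest$blacklist_flag <- manifest$blacklist_flag |
            manifest$probe_id %in% read_blacklist(blk$blacklist)
        }
        res <- run_qc(beta, det, manifest,
                      det_threshold = blk$det_p %||% 0.01,
                      max_sample_missing = blk$max_sample_missing %||% 0.015,
                      max_probe_fail = blk$max_probe_fail %||% 0.10)
        beta <- res$beta
        samples <- samples[samples$sample_id %in% colnames(res$beta), ]
        emit(glance(res$report), "qc_report.tsv")
        emit(res$beta, "beta_qc.tsv")
      },
      normalize = {
        cfg <- batch_adjust_config(
          subset_size = blk$subset_size %||% 20000,
          mode = blk$mode %||% "nonparametric",
          seed = blk$seed,
          mc_draws = blk$mc_draws %||% 1000)
        seeds$normalize <- cfg$seed
        beta <- batch_adjust(beta, samples, cfg, manifest = manifest)
        fit <- if (isTRUE(blk$fit_chemistry)) {
          fit_chemistry_correction(beta, manifest,
                                   max_distance_bp = blk$max_pair_distance %||% 50)
        } else {
          published_chemistry_fit()
        }
        emit(tidy(fit), "chemistry_fit.tsv")
        beta <- apply_chemistry_correction(beta, manifest, fit)
        emit(beta, "beta_normalized.tsv")
      },
      associate = {
        ctr <- contrast_spec(
          predictor = blk$contrast %||% "disease",
          covariates = blk$covariates %||% c("age", "sex", "ethnicity"),
          chromosome_scope = blk$scope %||% "autosomal")
        assoc <- run_association(beta, samples, ctr, manifest = manifest)
        emit(assoc, "association.tsv")
        n_perm <- blk$n_perm %||% 0
        if (n_perm > 0) {
          seeds$associate <- blk$seed
          perm <- permutation_pvalues(beta, samples, ctr, n_perm = n_perm,
                                      seed = blk$seed)
          emit(perm, "permutation.tsv")
        }
      },
      characterize = {
        emit(qq_data(assoc$p_value[!is.na(assoc$p_value)]), "qq.tsv")
        emit(directionality_profile(assoc, bin_width = blk$bin_width %||% 1.0),
             "directionality.tsv")
        emit(biphasic_band(assoc, blk$p_low %||% 1e-11, blk$p_high %||% 1e-8),
             "biphasic_band.tsv")
        ctrl_ids <- samples$sample_id[samples$disease == "control"]
        emit(intermediate_methylation_enrichment(assoc, beta, ctrl_ids),
             "intermediate_enrichment.tsv")
      },
      enrich = {
        genes <- read_bed(blk$annotation)
        mapping <- map_cpgs_to_genes(manifest, genes,
                                     window_bp = blk$window %||% 5000)
        emit(mapping, "cpg_gene_mapping.tsv")
        gene_sets <- read_gmt(blk$gene_sets)
        top <- top_k_probes(assoc, k = blk$top_k %||% 100)
        emit(gene_set_enrichment(top, mapping, gene_sets, assoc$probe_id),
             "gene_set_enrichment.tsv")
      },
      replicate = {
        validation <- readr::read_tsv(blk$validation, col_types = readr::cols(),
                                      progress = FALSE)
        emit(replication_stats(assoc, validation,
                               alpha = blk$alpha %||% 0.01),
             "replication.tsv")
      }
    ))
  }

  manifest_json <- list(
    package = "methylewas",
    version = as.character(utils::packageVersion("methylewas")),
    config_hash = rlang::hash(config),
    stages = config$stages,
    seeds = seeds,
    outputs = unname(outputs),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest_json,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest_json)
}
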