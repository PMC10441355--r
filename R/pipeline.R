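## Stage orchestration: a YAML pipeline config drives simulate / train /
## cv / predict / rejuvenate / ewas / glycan stages. Every stage writes its
## declared output files plus a run-manifest JSON (inputs, seed, parameter
## values) sufficient to re-execute it; all randomness flows from the
## config seed.

#' Read (or build) a pipeline configuration
#'
#' Either pass a YAML file path or a named list. The config carries paths
#' (`beta`, `samples`, `glycans`, `out_dir`), clock settings (`transform`,
#' `tissues`, `cv_scheme`, `nfolds`), EWAS settings (`k`, `n_controls`,
#' `fdr`) and simulation settings (forwarded to the generator configs).
#' A `seed` is required: no stage runs on an implicit seed.
#'
#' @param x YAML path or named list.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("config must be a YAML file or a named list", call. = FALSE)
  if (is.null(cfg$seed)) stop("config must set an explicit integer `seed`",
                              call. = FALSE)
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg$transform <- cfg$transform %||% "identity"
  cfg$cv_scheme <- cfg$cv_scheme %||% "loocv"
  cfg$nfolds <- cfg$nfolds %||% 10
  cfg$k <- cfg$k %||% 2
  cfg$n_controls <- cfg$n_controls %||% 500
  cfg$fdr <- cfg$fdr %||% 0.05
  structure(cfg, class = "pipeline_config")
}

write_manifest <- function(cfg, stage, inputs, outputs) {
  manifest <- list(
    stage = stage,
    seed = cfg$seed,
    parameters = unclass(cfg)[setdiff(names(cfg),
                                      c("simulation", "glycan_simulation"))],
    inputs = inputs,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("rejuvclock"))
  )
  path <- file.path(cfg$out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  path
}

load_stage_inputs <- function(cfg) {
  beta <- impute_missing(read_beta_matrix(cfg$beta))
  ann <- read_sample_annotation(cfg$samples)
  list(beta = beta, annotation = ann)
}

config_transform <- function(cfg) age_transform(cfg$transform)

#' Run the simulate stage
#'
#' Writes a methylation dataset (`sim_beta.tsv`, `sim_samples.csv`,
#' `sim_truth.json`) built from `cfg$simulation` (fields of
#' [methyl_sim_config()], plus optional `study = "treatment"` with
#' [treatment_sim_config()] fields) into `cfg$out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @return Named vector of written paths, invisibly.
#' @export
run_simulate <- function(cfg) {
  cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- cfg$simulation %||% list()
  study <- sim_args$study %||% "panel"
  sim_args$study <- NULL
  if (identical(study, "treatment")) {
    tx_fields <- intersect(names(sim_args),
                           c("n_per_group", "young_age", "old_age",
                             "planted_rejuvenation"))
    base_args <- sim_args[setdiff(names(sim_args), tx_fields)]
    if (!is.null(base_args$tissues)) base_args$tissues <- unlist(base_args$tissues)
    base_args$seed <- sim_args$seed %||% cfg$seed
    base <- do.call(methyl_sim_config, base_args)
    tx <- do.call(treatment_sim_config,
                  c(list(base = base, seed = cfg$seed), sim_args[tx_fields]))
    sim <- simulate_treatment_study(tx)
  } else {
    sim_args$seed <- sim_args$seed %||% cfg$seed
    if (!is.null(sim_args$tissues)) sim_args$tissues <- unlist(sim_args$tissues)
    sim <- simulate_methylomes(do.call(methyl_sim_config, sim_args))
  }
  paths <- write_simulated_dataset(sim, cfg$out_dir)
  write_manifest(cfg, "simulate", inputs = list(), outputs = as.list(paths))
  invisible(paths)
}

#' Run the train stage
#'
#' Fits a clock on the configured beta matrix/sample sheet and writes the
#' coefficient file (`clock.csv` + JSON sidecar).
#'
#' @param cfg A [pipeline_config()] with `beta` and `samples` paths.
#' @return Path of the coefficient file, invisibly.
#' @export
run_train <- function(cfg) {
  cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_stage_inputs(cfg)
  clock <- fit_clock(inp$beta, inp$annotation, config_transform(cfg),
                     tissues = cfg$tissues, nfolds = cfg$nfolds,
                     seed = cfg$seed)
  path <- file.path(cfg$out_dir, "clock.csv")
  save_clock(clock, path)
  write_manifest(cfg, "train",
                 inputs = list(beta = cfg$beta, samples = cfg$samples),
                 outputs = list(clock = path))
  invisible(path)
}

#' Run the cross-validation stage
#'
#' @param cfg A [pipeline_config()]; `cv_scheme` is `"loocv"` or an integer.
#' @return The `clock_cv` object, invisibly; writes `cv_report.json` and
#'   per-sample `cv_predictions.tsv`.
#' @export
run_cv <- function(cfg) {
  cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_stage_inputs(cfg)
  cv <- cross_validate_clock(inp$beta, inp$annotation, config_transform(cfg),
                             scheme = cfg$cv_scheme, tissues = cfg$tissues,
                             nfolds = cfg$nfolds, seed = cfg$seed)
  pred_path <- file.path(cfg$out_dir, "cv_predictions.tsv")
  readr::write_tsv(cv$predictions, pred_path)
  rep_path <- file.path(cfg$out_dir, "cv_report.json")
  jsonlite::write_json(
    list(scheme = cv$scheme, n = cv$n, pearson_r = cv$pearson_r,
         median_abs_error = cv$median_abs_error, seed = cv$seed),
    rep_path, auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, "cv",
                 inputs = list(beta = cfg$beta, samples = cfg$samples),
                 outputs = list(report = rep_path, predictions = pred_path))
  invisible(cv)
}

#' Run the predict stage
#'
#' @param cfg A [pipeline_config()] with a `clock` coefficient-file path.
#' @return Prediction tibble, invisibly; writes `predictions.tsv`.
#' @export
run_predict <- function(cfg) {
  cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_stage_inputs(cfg)
  clock <- load_clock(cfg$clock)
  pred <- predict_age(clock, inp$beta, inp$annotation)
  path <- file.path(cfg$out_dir, "predictions.tsv")
  readr::write_tsv(pred, path)
  write_manifest(cfg, "predict",
                 inputs = list(beta = cfg$beta, samples = cfg$samples,
                               clock = cfg$clock),
                 outputs = list(predictions = path))
  invisible(pred)
}

#' Run the rejuvenation stage
#'
#' Expects predictions for a three-arm study (either `cfg$predictions`, a
#' TSV with `tissue, clock, group, dnam_age`, or an in-memory tibble under
#' `cfg$prediction_table`); writes the per tissue x clock TSV and summary
#' JSON.
#'
#' @param cfg A [pipeline_config()].
#' @return The `rejuvenation_report`, invisibly.
#' @export
run_rejuvenate <- function(cfg) {
  cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pred <- if (!is.null(cfg$prediction_table)) cfg$prediction_table else
    readr::read_tsv(cfg$predictions, show_col_types = FALSE)
  report <- summarize_rejuvenation(pred)
  paths <- write_rejuvenation_report(
    report, file.path(cfg$out_dir, "rejuvenation.tsv"),
    file.path(cfg$out_dir, "rejuvenation_summary.json"))
  write_manifest(cfg, "rejuvenate",
                 inputs = list(predictions = cfg$predictions %||% "in-memory"),
                 outputs = as.list(paths))
  invisible(report)
}

#' Run the EWAS stage
#'
#' @param cfg A [pipeline_config()] with `beta`/`samples` paths and EWAS
#'   settings `k`, `n_controls`, `fdr`.
#' @return The [run_ewas()] result list, invisibly; writes per-contrast
#'   TSVs, the control-probe list and the reversal summary JSON.
#' @export
run_ewas_stage <- function(cfg) {
  cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_stage_inputs(cfg)
  res <- run_ewas(inp$beta, inp$annotation, k = cfg$k,
                  n_controls = cfg$n_controls, fdr = cfg$fdr)
  paths <- c(age = file.path(cfg$out_dir, "ewas_age.tsv"),
             elixir = file.path(cfg$out_dir, "ewas_elixir.tsv"),
             controls = file.path(cfg$out_dir, "ewas_control_probes.txt"),
             reversal = file.path(cfg$out_dir, "ewas_reversal.json"))
  readr::write_tsv(res$age, paths[["age"]])
  readr::write_tsv(res$elixir, paths[["elixir"]])
  writeLines(res$control_probes, paths[["controls"]])
  jsonlite::write_json(res$reversal, paths[["reversal"]], auto_unbox = TRUE,
                       digits = NA)
  write_manifest(cfg, "ewas",
                 inputs = list(beta = cfg$beta, samples = cfg$samples),
                 outputs = as.list(paths))
  invisible(res)
}

#' Run the glycan stage
#'
#' Reads a long-format glycan CSV (`cfg$glycans`), normalizes raw areas if
#' needed, and writes the cross-sectional age-association and longitudinal
#' mixed-model TSVs.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `association` and `mixed` tibbles, invisibly.
#' @export
run_glycan <- function(cfg) {
  cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_glycan_table(cfg$glycans)
  if (!"relative_abundance" %in% names(tab)) {
    tab <- normalize_to_subclass_total(tab)
  }
  assoc <- NULL
  if (all(c("age", "sex") %in% names(tab))) {
    assoc <- age_association_glm(tab[tab$timepoint == "baseline", ])
    readr::write_tsv(assoc, file.path(cfg$out_dir, "glycan_age_association.tsv"))
  }
  mixed <- treatment_mixed_model(tab)
  readr::write_tsv(mixed, file.path(cfg$out_dir, "glycan_mixed_model.tsv"))
  write_manifest(cfg, "glycan", inputs = list(glycans = cfg$glycans),
                 outputs = list(
                   association = if (is.null(assoc)) NULL else
                     file.path(cfg$out_dir, "glycan_age_association.tsv"),
                   mixed = file.path(cfg$out_dir, "glycan_mixed_model.tsv")))
  invisible(list(association = assoc, mixed = mixed))
}
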