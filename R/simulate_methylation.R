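## Synthetic methylome generator with planted ground truth.
##
## The generative model: for age-informative probe i and sample j,
##   beta_ij = clip01( inv_logit( b0_i + s_i * (age_j / maxLifespan)
##                                + tissue_offset_{i, t(j)} + batch_{i, b(j)} )
##             + eps_ij ),   eps_ij ~ Normal(0, noise_sd)
## with s_i = 0 for non-age probes. The aging signal is linear in
## logit(beta) against *relative* age (age / species maximum lifespan),
## which keeps betas bounded and makes a shared cross-species signal
## well-defined. Probe-level parameters (baselines, the identity and slope
## of age probes, tissue and batch offsets) are drawn from the config seed
## alone, so two calls with the same config but different `sample_seed`
## share one epigenome while drawing independent cohorts from it.

MAX_LIFESPAN_YEARS <- c(rat = 3.8, human = 122.5)

#' Configuration for the synthetic methylome generator
#'
#' Defaults describe the desk-scale multi-tissue rat panel used throughout
#' the package: 2,000 probes of which 200 carry an aging signal with logit
#' slope magnitudes drawn from Normal(4, 1) (half gaining, half losing
#' methylation with age), four tissues of 60 samples each, ages uniform on
#' 0.04--2.3 years, and beta-scale noise sd 0.03.
#'
#' @param n_probes Total probe count.
#' @param n_age_probes Number of probes carrying an aging signal.
#' @param frac_gain Fraction of age probes gaining methylation with age.
#' @param tissues Named integer vector of per-tissue sample counts.
#' @param age_range Length-2 numeric, min and max age in years.
#' @param species `"rat"` or `"human"` (sets the lifespan that scales
#'   relative age).
#' @param logit_slope_mean,logit_slope_sd Mean and sd of the absolute logit
#'   slope of age probes (per unit relative age).
#' @param baseline_logit_sd Sd of per-probe baseline logits (around 0).
#' @param center_age_probes Centre each age probe's baseline at minus its
#'   slope times the mid relative age of `age_range`, so the planted
#'   trajectory traverses the detectable mid-beta range rather than
#'   saturating — the regime in which array probes can register age drift
#'   (default `TRUE`).
#' @param tissue_offset_sd Sd of per-probe, per-tissue logit offsets.
#' @param batch_effect_sd Sd of per-probe, per-plate logit offsets.
#' @param n_batches Number of plates samples are cycled across.
#' @param noise_sd Beta-scale measurement noise sd.
#' @param seed Integer seed; drives every random draw.
#' @return A `methyl_sim_config` list.
#' @export
methyl_sim_config <- function(n_probes = 2000,
                              n_age_probes = 200,
                              frac_gain = 0.5,
                              tissues = c(blood = 60, liver = 60,
                                          heart = 60, hypothalamus = 60),
                              age_range = c(0.04, 2.3),
                              species = "rat",
                              logit_slope_mean = 4,
                              logit_slope_sd = 1,
                              baseline_logit_sd = 0.8,
                              center_age_probes = TRUE,
                              tissue_offset_sd = 0.3,
                              batch_effect_sd = 0.1,
                              n_batches = 4,
                              noise_sd = 0.03,
                              seed = 1) {
  cfg <- list(n_probes = n_probes, n_age_probes = n_age_probes,
              frac_gain = frac_gain, tissues = tissues,
              age_range = age_range, species = species,
              logit_slope_mean = logit_slope_mean,
              logit_slope_sd = logit_slope_sd,
              baseline_logit_sd = baseline_logit_sd,
              center_age_probes = isTRUE(center_age_probes),
              tissue_offset_sd = tissue_offset_sd,
              batch_effect_sd = batch_effect_sd, n_batches = n_batches,
              noise_sd = noise_sd, seed = seed)
  validate_methyl_sim_config(cfg)
  structure(cfg, class = "methyl_sim_config")
}

validate_methyl_sim_config <- function(cfg) {
  assert_scalar_number(cfg$n_probes, "n_probes", min = 1)
  assert_scalar_number(cfg$n_age_probes, "n_age_probes", min = 0,
                       max = cfg$n_probes)
  assert_scalar_number(cfg$frac_gain, "frac_gain", min = 0, max = 1)
  assert_scalar_number(cfg$noise_sd, "noise_sd", min = 0)
  if (is.null(names(cfg$tissues)) || any(cfg$tissues < 1)) {
    stop("`tissues` must be a named vector of positive sample counts",
         call. = FALSE)
  }
  if (length(cfg$age_range) != 2 || cfg$age_range[1] > cfg$age_range[2] ||
      cfg$age_range[1] < 0) {
    stop("`age_range` must be (min, max) with 0 <= min <= max", call. = FALSE)
  }
  if (!cfg$species %in% names(MAX_LIFESPAN_YEARS)) {
    stop("unknown species: ", cfg$species, call. = FALSE)
  }
  if (cfg$age_range[2] > MAX_LIFESPAN_YEARS[[cfg$species]]) {
    stop("age_range exceeds the species maximum lifespan", call. = FALSE)
  }
  assert_scalar_number(cfg$seed, "seed")
  invisible(cfg)
}

# Probe-level parameters drawn from the config seed alone.
probe_params <- function(cfg) {
  local_seed(cfg$seed, {
    probe_ids <- sprintf("cg%05d", seq_len(cfg$n_probes))
    b0 <- stats::rnorm(cfg$n_probes, 0, cfg$baseline_logit_sd)
    age_idx <- sort(sample.int(cfg$n_probes, cfg$n_age_probes))
    n_gain <- round(cfg$frac_gain * cfg$n_age_probes)
    sign_vec <- rep(c(1, -1), c(n_gain, cfg$n_age_probes - n_gain))
    magnitude <- abs(stats::rnorm(cfg$n_age_probes, cfg$logit_slope_mean,
                                  cfg$logit_slope_sd))
    slopes <- numeric(cfg$n_probes)
    slopes[age_idx] <- sign_vec * magnitude
    if (cfg$center_age_probes) {
      # age probes drift through mid-beta: baseline offset by -slope * mid
      # relative age keeps the trajectory inside the detectable range
      mid_rel <- mean(cfg$age_range) / MAX_LIFESPAN_YEARS[[cfg$species]]
      b0 <- b0 - slopes * mid_rel
    }
    tissue_names <- names(cfg$tissues)
    tissue_offsets <- matrix(
      stats::rnorm(cfg$n_probes * length(tissue_names), 0, cfg$tissue_offset_sd),
      nrow = cfg$n_probes,
      dimnames = list(probe_ids, tissue_names))
    batch_effects <- matrix(
      stats::rnorm(cfg$n_probes * cfg$n_batches, 0, cfg$batch_effect_sd),
      nrow = cfg$n_probes,
      dimnames = list(probe_ids, paste0("plate", seq_len(cfg$n_batches))))
    list(probe_ids = probe_ids, b0 = b0, slopes = slopes,
         age_idx = age_idx, tissue_offsets = tissue_offsets,
         batch_effects = batch_effects)
  })
}

# Deterministic sample layout (ids, tissues, plates, columns) for a config.
sample_layout <- function(cfg, id_prefix = cfg$species) {
  tissue <- rep(names(cfg$tissues), times = cfg$tissues)
  n <- length(tissue)
  tibble::tibble(
    sample_id = sprintf("%s_%04d", id_prefix, seq_len(n)),
    species = cfg$species,
    tissue = tissue,
    batch_plate = paste0("plate", 1 + (seq_len(n) - 1) %% cfg$n_batches),
    batch_column = paste0("col", 1 + ((seq_len(n) - 1) %/% cfg$n_batches) %% 2)
  )
}

# Core emitter: betas for given ages/tissues/plates under shared probe params.
emit_betas <- function(cfg, params, layout, ages) {
  rel_age <- ages / MAX_LIFESPAN_YEARS[[cfg$species]]
  mu_logit <- outer(params$b0, rep(1, length(ages))) +
    outer(params$slopes, rel_age) +
    params$tissue_offsets[, layout$tissue, drop = FALSE] +
    params$batch_effects[, layout$batch_plate, drop = FALSE]
  eps <- matrix(stats::rnorm(length(mu_logit), 0, cfg$noise_sd),
                nrow = nrow(mu_logit))
  beta <- clip01(inv_logit(mu_logit) + eps)
  dimnames(beta) <- list(params$probe_ids, layout$sample_id)
  beta
}

#' Simulate a multi-tissue methylome panel with planted age probes
#'
#' Ages are drawn uniformly on `cfg$age_range`. The returned truth record
#' lists exactly the planted age probes and their logit slopes, sufficient
#' to score downstream probe-recovery and EWAS stages.
#'
#' @param cfg A [methyl_sim_config()].
#' @param sample_seed Seed for the sample-level draws (ages and noise);
#'   defaults to `cfg$seed` so identical configs give bit-identical output.
#'   Pass a different value to draw an independent cohort from the same
#'   simulated epigenome.
#' @return List with `beta` (probes x samples matrix), `annotation`
#'   (tibble), and `truth` (list with `age_probes` tibble and the config).
#' @export
simulate_methylomes <- function(cfg, sample_seed = cfg$seed) {
  validate_methyl_sim_config(cfg)
  params <- probe_params(cfg)
  layout <- sample_layout(cfg)
  local_seed(sample_seed, {
    ages <- stats::runif(nrow(layout), cfg$age_range[1], cfg$age_range[2])
    beta <- emit_betas(cfg, params, layout, ages)
    annotation <- validate_sample_annotation(
      dplyr::mutate(layout, age = ages, group = "none"))
    truth <- list(
      age_probes = tibble::tibble(
        probe_id = params$probe_ids[params$age_idx],
        logit_slope = params$slopes[params$age_idx]),
      config = cfg)
    list(beta = beta, annotation = annotation, truth = truth)
  })
}

#' Configuration for the three-arm treatment simulation
#'
#' Defaults follow the study design the generator emulates: three arms of
#' six rats each, young at 0.58 years (30 weeks), old controls and treated
#' old animals at 2.1 years (109 weeks). The treated arm's methylomes are
#' generated at effective age `old_age * (1 - planted_rejuvenation / 100)`
#' but annotated with chronological age `old_age`, so the planted
#' percentage is exactly the quantity the rejuvenation statistic estimates.
#'
#' @param base A [methyl_sim_config()] describing the probe panel and noise.
#' @param n_per_group Samples per arm per tissue.
#' @param young_age,old_age Arm ages in years.
#' @param planted_rejuvenation Planted rejuvenation percentage in `[0, 100]`.
#' @param seed Seed for the sample-level draws of the study.
#' @return A `treatment_sim_config` list.
#' @export
treatment_sim_config <- function(base = methyl_sim_config(),
                                 n_per_group = 6,
                                 young_age = 0.58,
                                 old_age = 2.1,
                                 planted_rejuvenation = 50,
                                 seed = 1) {
  assert_scalar_number(planted_rejuvenation, "planted_rejuvenation", 0, 100)
  assert_scalar_number(n_per_group, "n_per_group", min = 1)
  if (!(young_age < old_age)) stop("young_age must be below old_age", call. = FALSE)
  validate_methyl_sim_config(base)
  structure(list(base = base, n_per_group = n_per_group,
                 young_age = young_age, old_age = old_age,
                 planted_rejuvenation = planted_rejuvenation, seed = seed),
            class = "treatment_sim_config")
}

#' Simulate a young / old-control / old-treated methylation study
#'
#' Each tissue in `cfg$base$tissues` receives all three arms with
#' `cfg$n_per_group` samples each. Probe-level parameters come from
#' `cfg$base$seed`, so a clock trained on an independent
#' [simulate_methylomes()] panel built from the same base config applies
#' directly to the study samples.
#'
#' @param cfg A [treatment_sim_config()].
#' @return List with `beta`, `annotation` (with `group` filled) and `truth`
#'   (planted rejuvenation, effective treated age, age probes).
#' @export
simulate_treatment_study <- function(cfg) {
  stopifnot(inherits(cfg, "treatment_sim_config"))
  base <- cfg$base
  params <- probe_params(base)
  groups <- c("young_control", "old_control", "old_treated")
  tissue_names <- names(base$tissues)
  grid <- tidyr::expand_grid(tissue = tissue_names, group = groups,
                             rep = seq_len(cfg$n_per_group))
  n <- nrow(grid)
  layout <- tibble::tibble(
    sample_id = sprintf("%s_tx_%04d", base$species, seq_len(n)),
    species = base$species,
    tissue = grid$tissue,
    batch_plate = paste0("plate", 1 + (seq_len(n) - 1) %% base$n_batches),
    batch_column = paste0("col", 1 + ((seq_len(n) - 1) %/% base$n_batches) %% 2)
  )
  effective_age <- cfg$old_age * (1 - cfg$planted_rejuvenation / 100)
  gen_age <- dplyr::case_match(grid$group,
    "young_control" ~ cfg$young_age,
    "old_control" ~ cfg$old_age,
    "old_treated" ~ effective_age)
  chron_age <- ifelse(grid$group == "young_control", cfg$young_age, cfg$old_age)
  local_seed(cfg$seed, {
    beta <- emit_betas(base, params, layout, gen_age)
    annotation <- validate_sample_annotation(
      dplyr::mutate(layout, age = chron_age, group = grid$group))
    truth <- list(
      planted_rejuvenation = cfg$planted_rejuvenation,
      effective_treated_age = effective_age,
      age_probes = tibble::tibble(
        probe_id = params$probe_ids[params$age_idx],
        logit_slope = params$slopes[params$age_idx]),
      config = cfg)
    list(beta = beta, annotation = annotation, truth = truth)
  })
}

#' Simulate a combined two-species methylation panel
#'
#' Both species are generated on the same probe panel. With
#' `shared_relative_age_signal = TRUE` the identical probes carry the
#' identical logit slope against relative age (age / species lifespan) in
#' both species, the structure a relative-age clock exploits; with `FALSE`
#' each species receives an independently drawn aging signal.
#'
#' @param cfg_rat,cfg_human [methyl_sim_config()]s with equal `n_probes`.
#' @param shared_relative_age_signal Logical.
#' @return List with combined `beta`, `annotation` and `truth` (per-species
#'   age-probe records).
#' @export
simulate_two_species <- function(cfg_rat, cfg_human,
                                 shared_relative_age_signal = TRUE) {
  validate_methyl_sim_config(cfg_rat)
  validate_methyl_sim_config(cfg_human)
  if (cfg_rat$n_probes != cfg_human$n_probes) {
    stop("the two configs must describe the same probe panel (n_probes differ)",
         call. = FALSE)
  }
  sim_rat <- simulate_methylomes(cfg_rat)
  if (shared_relative_age_signal) {
    cfg_human_shared <- cfg_human
    # reuse the rat probe parameters: same baselines, same age probes/slopes
    params <- probe_params(cfg_rat)
    layout <- sample_layout(cfg_human)
    sim_human <- local_seed(cfg_human$seed, {
      ages <- stats::runif(nrow(layout), cfg_human$age_range[1],
                           cfg_human$age_range[2])
      # human tissue/batch offsets must exist for human tissue names
      params_h <- params
      hp <- probe_params(cfg_human_shared)
      params_h$tissue_offsets <- hp$tissue_offsets
      params_h$batch_effects <- hp$batch_effects
      beta <- emit_betas(cfg_human, params_h, layout, ages)
      list(beta = beta,
           annotation = validate_sample_annotation(
             dplyr::mutate(layout, age = ages, group = "none")),
           truth = list(age_probes = tibble::tibble(
             probe_id = params$probe_ids[params$age_idx],
             logit_slope = params$slopes[params$age_idx])))
    })
  } else {
    sim_human <- simulate_methylomes(cfg_human)
  }
  list(
    beta = cbind(sim_rat$beta, sim_human$beta),
    annotation = dplyr::bind_rows(sim_rat$annotation, sim_human$annotation),
    truth = list(rat = sim_rat$truth$age_probes,
                 human = sim_human$truth$age_probes,
                 shared_relative_age_signal = shared_relative_age_signal)
  )
}

#' Write a simulated methylation dataset to disk
#'
#' Emits the TSV/CSV formats the I/O layer reads plus a JSON truth record.
#'
#' @param sim Output of one of the `simulate_*` generators.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    beta = file.path(dir, paste0(prefix, "_beta.tsv")),
    annotation = file.path(dir, paste0(prefix, "_samples.csv")),
    truth = file.path(dir, paste0(prefix, "_truth.json"))
  )
  write_beta_matrix(sim$beta, paths[["beta"]])
  write_sample_annotation(sim$annotation, paths[["annotation"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(paths)
}
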