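# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk except files the tests themselves write.

# Small single-tissue panel for fast clock tests.
small_panel_config <- function(seed = 3, n = 40, n_probes = 300,
                               n_age_probes = 40) {
  methyl_sim_config(n_probes = n_probes, n_age_probes = n_age_probes,
                    tissues = c(blood = n), seed = seed)
}

# Noiseless config: no tissue/batch/baseline variation, fixed slope 4 on
# every age probe (gain only), so expectations are closed-form.
noiseless_config <- function(n_probes = 5, n_age_probes = 1, n = 3,
                             age_range = c(1.9, 1.9), seed = 1,
                             species = "rat") {
  methyl_sim_config(
    n_probes = n_probes, n_age_probes = n_age_probes, frac_gain = 1,
    tissues = c(blood = n), age_range = age_range, species = species,
    logit_slope_mean = 4, logit_slope_sd = 0, baseline_logit_sd = 0,
    center_age_probes = FALSE,
    tissue_offset_sd = 0, batch_effect_sd = 0, noise_sd = 0, seed = seed)
}

# A small random beta matrix with names, for I/O and algebra tests.
random_beta <- function(n_probes = 20, n_samples = 8, seed = 11) {
  m <- local({
    set.seed(seed)
    matrix(runif(n_probes * n_samples), nrow = n_probes,
           dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                           sprintf("s%03d", seq_len(n_samples))))
  })
  m
}

annotation_for <- function(m, species = "rat", tissue = "blood",
                           ages = NULL, group = "none", seed = 5) {
  n <- ncol(m)
  if (is.null(ages)) {
    set.seed(seed)
    ages <- runif(n, 0.1, 2.3)
  }
  tibble::tibble(sample_id = colnames(m), species = species, tissue = tissue,
                 age = ages, sex = "unknown", batch_plate = "unknown",
                 batch_column = "unknown", group = group,
                 subject_id = colnames(m), timepoint = NA_character_)
}
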