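## Synthetic IgG Fc N-glycan study generator.
##
## Emulates a longitudinal two-timepoint, two-arm (treated vs control)
## glycoform panel over the three rat IgG subclasses. Proportions live on a
## per-subclass simplex; aging drifts the control arm toward
## agalactosylation (G0 up, G2 down) between baseline and follow-up, and
## the planted treatment effect shifts the treated arm's follow-up on top
## of that. Drift vectors sum to zero per subclass so the simplex
## renormalization is the identity in expectation and planted effects stay
## exactly interpretable.

#' Configuration for the synthetic glycan study
#'
#' @param n_per_arm Subjects per arm (treated, control).
#' @param subclasses IgG subclasses carried by the panel.
#' @param glycoforms Glycoform labels (galactosylation states).
#' @param baseline_props Named list, per subclass, of baseline glycoform
#'   proportions (each summing to 1).
#' @param age_slopes Named vector, per glycoform: proportion drift from
#'   baseline to follow-up in the untreated arm (sums to 0).
#' @param cross_age_slopes Named vector, per glycoform: proportion change
#'   per year of baseline age (cross-sectional aging signal; sums to 0).
#' @param treatment_effect Named vector, per glycoform: extra follow-up
#'   shift in the treated arm (sums to 0). Default plants the reversal the
#'   pipeline should detect: G0 down, G2 up.
#' @param age_range Baseline ages (years) drawn uniformly per subject.
#' @param subject_intercept_sd Sd of per-subject glycoform intercepts.
#' @param residual_sd Sd of per-measurement noise (proportion scale).
#' @param seed Integer seed.
#' @return A `glycan_sim_config` list.
#' @export
glycan_sim_config <- function(n_per_arm = 8,
                              subclasses = c("IgG2a", "IgG2b", "IgG2c"),
                              glycoforms = c("G0", "G1", "G2"),
                              baseline_props = NULL,
                              age_slopes = c(G0 = 0.05, G1 = 0, G2 = -0.05),
                              cross_age_slopes = c(G0 = 0.04, G1 = 0, G2 = -0.04),
                              treatment_effect = c(G0 = -0.05, G1 = 0, G2 = 0.05),
                              age_range = c(1.8, 2.2),
                              subject_intercept_sd = 0.02,
                              residual_sd = 0.02,
                              seed = 1) {
  if (is.null(baseline_props)) {
    baseline_props <- stats::setNames(
      rep(list(stats::setNames(c(0.35, 0.40, 0.25), glycoforms)), length(subclasses)),
      subclasses)
  }
  cfg <- structure(
    list(n_per_arm = n_per_arm, subclasses = subclasses,
         glycoforms = glycoforms, baseline_props = baseline_props,
         age_slopes = age_slopes, cross_age_slopes = cross_age_slopes,
         treatment_effect = treatment_effect, age_range = age_range,
         subject_intercept_sd = subject_intercept_sd,
         residual_sd = residual_sd, seed = seed),
    class = "glycan_sim_config")
  validate_glycan_sim_config(cfg)
  cfg
}

validate_glycan_sim_config <- function(cfg) {
  assert_scalar_number(cfg$n_per_arm, "n_per_arm", min = 2)
  assert_scalar_number(cfg$subject_intercept_sd, "subject_intercept_sd", min = 0)
  assert_scalar_number(cfg$residual_sd, "residual_sd", min = 0)
  for (sc in cfg$subclasses) {
    p <- cfg$baseline_props[[sc]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-9 || any(p <= 0)) {
      stop("baseline_props for ", sc, " must be positive and sum to 1",
           call. = FALSE)
    }
    # expected proportions must stay inside (0,1) before renormalization
    worst <- p[cfg$glycoforms] +
      cfg$age_slopes[cfg$glycoforms] +
      pmin(0, cfg$treatment_effect[cfg$glycoforms]) +
      pmin(0, cfg$cross_age_slopes[cfg$glycoforms]) * diff(range(cfg$age_range))
    best <- p[cfg$glycoforms] + pmax(0, cfg$age_slopes[cfg$glycoforms]) +
      pmax(0, cfg$treatment_effect[cfg$glycoforms]) +
      pmax(0, cfg$cross_age_slopes[cfg$glycoforms]) * diff(range(cfg$age_range))
    if (any(worst <= 0) || any(best >= 1)) {
      stop("configured shifts push expected ", sc,
           " proportions outside (0, 1)", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Simulate a longitudinal two-arm glycan study
#'
#' Each subject contributes one baseline and one follow-up measurement per
#' subclass x glycoform. Per-subject random intercepts induce the
#' within-subject correlation a mixed model with random intercept absorbs.
#' Proportions are renormalized to the per-subclass simplex after noise.
#'
#' @param cfg A [glycan_sim_config()].
#' @return List with `table` (long tibble: `sample_id, subject_id, arm,
#'   timepoint, age, sex, subclass, glycoform, relative_abundance`) and
#'   `truth` (the planted slopes and treatment effect).
#' @export
simulate_glycan_study <- function(cfg) {
  validate_glycan_sim_config(cfg)
  arms <- c("control", "treated")
  subjects <- tidyr::expand_grid(arm = arms, idx = seq_len(cfg$n_per_arm))
  subjects$subject_id <- sprintf("subj_%s_%02d", subjects$arm, subjects$idx)
  local_seed(cfg$seed, {
    subjects$age <- stats::runif(nrow(subjects), cfg$age_range[1],
                                 cfg$age_range[2])
    subjects$sex <- rep_len(c("male", "female"), nrow(subjects))
    mid_age <- mean(cfg$age_range)
    rows <- tidyr::expand_grid(
      subjects,
      timepoint = c("baseline", "followup"),
      subclass = cfg$subclasses,
      glycoform = cfg$glycoforms
    )
    n_int <- nrow(subjects) * length(cfg$subclasses) * length(cfg$glycoforms)
    intercepts <- tidyr::expand_grid(subject_id = subjects$subject_id,
                                     subclass = cfg$subclasses,
                                     glycoform = cfg$glycoforms)
    intercepts$u <- stats::rnorm(n_int, 0, cfg$subject_intercept_sd)
    rows <- dplyr::left_join(rows, intercepts,
                             by = c("subject_id", "subclass", "glycoform"))
    base_p <- purrr::map2_dbl(rows$subclass, rows$glycoform,
                              function(sc, gf) cfg$baseline_props[[sc]][[gf]])
    drift <- ifelse(rows$timepoint == "followup",
                    cfg$age_slopes[rows$glycoform], 0)
    treat <- ifelse(rows$timepoint == "followup" & rows$arm == "treated",
                    cfg$treatment_effect[rows$glycoform], 0)
    aging <- cfg$cross_age_slopes[rows$glycoform] * (rows$age - mid_age)
    mu <- base_p + aging + drift + treat + rows$u
    value <- mu + stats::rnorm(nrow(rows), 0, cfg$residual_sd)
    value <- pmax(value, 1e-6)
    out <- rows
    out$raw <- value
    out <- dplyr::mutate(
      dplyr::group_by(out, subject_id, timepoint, subclass),
      relative_abundance = raw / sum(raw))
    out <- dplyr::ungroup(out)
    table <- tibble::tibble(
      sample_id = paste0(out$subject_id, "_", out$timepoint),
      subject_id = out$subject_id,
      arm = out$arm,
      timepoint = out$timepoint,
      age = out$age,
      sex = out$sex,
      subclass = out$subclass,
      glycoform = out$glycoform,
      relative_abundance = out$relative_abundance
    )
    truth <- list(age_slopes = cfg$age_slopes,
                  cross_age_slopes = cfg$cross_age_slopes,
                  treatment_effect = cfg$treatment_effect,
                  config = cfg)
    list(table = table, truth = truth)
  })
}
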