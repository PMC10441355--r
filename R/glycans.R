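## IgG Fc N-glycan aging analysis.
##
## Raw chromatogram areas are normalized to the total area within each
## sample x IgG subclass; each glycoform trait is transformed to standard
## normal by rank-based inverse-normal transformation so effect estimates
## are comparable across glycoforms; cross-sectional age association uses
## a linear model with sex as covariate, and the longitudinal treatment
## analysis a linear mixed-effects model with fixed time, fixed
## time x treatment interaction and a per-subject random intercept (REML).
## p-values for mixed-model fixed effects use the normal approximation to
## the Wald statistic; FDR is controlled by Benjamini-Hochberg across the
## glycoform panel.

GLYCAN_COLUMNS <- c("sample_id", "subject_id", "arm", "timepoint",
                    "subclass", "glycoform")

#' Read a long-format glycan area table
#'
#' CSV with columns `sample_id, subject_id, arm, timepoint, subclass,
#' glycoform, area` (raw integrated areas) or `relative_abundance`
#' (already normalized).
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_glycan_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  for (num in intersect(c("area", "relative_abundance", "age"), names(df))) {
    df[[num]] <- as.numeric(df[[num]])
  }
  missing_cols <- setdiff(GLYCAN_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("glycan table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!any(c("area", "relative_abundance") %in% names(df))) {
    stop("glycan table needs an `area` or `relative_abundance` column",
         call. = FALSE)
  }
  df
}

#' Normalize glycoform areas to the subclass total
#'
#' Each raw area is divided by the total area of its sample x subclass, so
#' relative abundances sum to 1 within every subclass of every sample.
#'
#' @param areas Tibble with `sample_id`, `subclass`, `glycoform`, `area`.
#' @return The input with a `relative_abundance` column (and `area`
#'   dropped).
#' @export
normalize_to_subclass_total <- function(areas) {
  if (!"area" %in% names(areas)) stop("`area` column required", call. = FALSE)
  if (any(areas$area < 0)) stop("areas must be non-negative", call. = FALSE)
  out <- dplyr::mutate(dplyr::group_by(areas, sample_id, subclass),
                       total = sum(area))
  out <- dplyr::ungroup(out)
  if (any(out$total == 0)) {
    bad <- dplyr::distinct(out[out$total == 0, ], sample_id, subclass)
    stop("all-zero subclass total for ",
         paste(bad$sample_id, bad$subclass, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  out$relative_abundance <- out$area / out$total
  dplyr::select(out, -total, -area)
}

#' Rank-based inverse-normal transformation
#'
#' Maps value i to `qnorm((rank_i - 0.5) / n)` with average ranks for ties,
#' yielding a standard-normal-shaped trait (mean 0, sd 1 for tie-free
#' input), the transform applied to every glycopeptide trait before
#' association analysis.
#'
#' @param x Numeric vector, length >= 2, not all values identical.
#' @return Transformed vector.
#' @export
rank_inverse_normal <- function(x) {
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  if (length(unique(x)) == 1) stop("constant input cannot be rank-transformed",
                                   call. = FALSE)
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 0.5) / length(x))
}

#' Cross-sectional age association of glycoform traits
#'
#' Per subclass x glycoform: the inverse-normal-transformed relative
#' abundance is regressed on chronological age (years) with sex as an
#' additional covariate; BH-adjusted q-values are computed across the
#' panel. The age coefficient is per year of age on the transformed
#' (standard-normal) trait scale.
#'
#' @param table Glycoform tibble at a single timepoint with columns
#'   `subclass`, `glycoform`, `relative_abundance`, `age`, `sex`.
#' @return Tibble `subclass, glycoform, age_coefficient, p, q`.
#' @export
age_association_glm <- function(table) {
  needed <- c("subclass", "glycoform", "relative_abundance", "age", "sex")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    stop("glycan table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  res <- dplyr::group_modify(
    dplyr::group_by(table, subclass, glycoform),
    function(df, key) {
      if (nrow(df) < 4) stop("need n >= 4 per glycoform", call. = FALSE)
      y <- rank_inverse_normal(df$relative_abundance)
      has_sex <- length(unique(df$sex)) > 1
      fit <- if (has_sex) {
        stats::lm(y ~ age + factor(sex), data = df)
      } else {
        stats::lm(y ~ age, data = df)
      }
      sm <- summary(fit)$coefficients
      tibble::tibble(age_coefficient = sm["age", "Estimate"],
                     p = sm["age", "Pr(>|t|)"])
    })
  res <- dplyr::ungroup(res)
  res$q <- bh_adjust(res$p)
  res
}

#' Longitudinal mixed-effects treatment analysis
#'
#' Per subclass x glycoform the inverse-normal-transformed abundance is
#' modelled as fixed time (baseline vs follow-up), fixed time x treatment
#' interaction, and a random per-subject intercept, fitted by REML. The
#' interaction coefficient is the planted quantity of interest: the extra
#' follow-up shift in the treated arm, on the transformed scale (or on the
#' proportion scale with `transform = FALSE`). Non-convergence is reported
#' per glycoform without failing the remaining panel.
#'
#' @param table Two-timepoint glycoform tibble with columns `subject_id`,
#'   `arm` (`"treated"` / `"control"`), `timepoint` (`"baseline"` /
#'   `"followup"`), `subclass`, `glycoform`, `relative_abundance`.
#' @param transform Apply [rank_inverse_normal()] per glycoform (default
#'   `TRUE`).
#' @return Tibble `subclass, glycoform, time_effect, time_p,
#'   interaction_effect, interaction_p, interaction_q,
#'   random_intercept_var, converged`.
#' @export
treatment_mixed_model <- function(table, transform = TRUE) {
  needed <- c("subject_id", "arm", "timepoint", "subclass", "glycoform",
              "relative_abundance")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    stop("glycan table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  counts <- dplyr::count(
    dplyr::distinct(table, subject_id, arm, timepoint), arm)
  if (any(counts$n < 4)) {
    stop("need >= 2 subjects per arm with both timepoints", call. = FALSE)
  }
  res <- dplyr::group_modify(
    dplyr::group_by(table, subclass, glycoform),
    function(df, key) {
      df$time <- as.integer(df$timepoint == "followup")
      df$treated <- as.integer(df$arm == "treated")
      df$y <- if (transform) rank_inverse_normal(df$relative_abundance) else
        df$relative_abundance
      out <- tibble::tibble(time_effect = NA_real_, time_p = NA_real_,
                            interaction_effect = NA_real_,
                            interaction_p = NA_real_,
                            random_intercept_var = NA_real_,
                            converged = FALSE)
      fit <- tryCatch(
        suppressMessages(lme4::lmer(
          y ~ time + time:treated + (1 | subject_id), data = df, REML = TRUE,
          control = lme4::lmerControl(check.conv.singular = "ignore"))),
        error = function(e) NULL)
      if (is.null(fit)) return(out)
      fe <- lme4::fixef(fit)
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))
      z <- fe / se
      p <- 2 * stats::pnorm(-abs(z))
      vc <- as.data.frame(lme4::VarCorr(fit))
      out$time_effect <- unname(fe["time"])
      out$time_p <- unname(p["time"])
      out$interaction_effect <- unname(fe["time:treated"])
      out$interaction_p <- unname(p["time:treated"])
      out$random_intercept_var <- vc$vcov[vc$grp == "subject_id"]
      out$converged <- TRUE
      out
    })
  res <- dplyr::ungroup(res)
  ok <- res$converged
  res$interaction_q <- NA_real_
  if (any(ok)) res$interaction_q[ok] <- bh_adjust(res$interaction_p[ok])
  res
}

#' Per-subject baseline-normalized change (export convenience)
#'
#' Follow-up minus baseline relative abundance per subject x subclass x
#' glycoform; a plotting/export aid, not part of inference.
#'
#' @param table Two-timepoint glycoform tibble.
#' @return Tibble `subject_id, arm, subclass, glycoform, change`.
#' @export
baseline_change <- function(table) {
  wide <- tidyr::pivot_wider(
    table[, c("subject_id", "arm", "timepoint", "subclass", "glycoform",
              "relative_abundance")],
    names_from = timepoint, values_from = relative_abundance)
  dplyr::transmute(wide, subject_id, arm, subclass, glycoform,
                   change = followup - baseline)
}
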