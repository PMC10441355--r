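## Clock scoring and treatment-effect quantification: correlation and
## median-absolute-error metrics, epigenetic age acceleration, group
## comparison statistics, and the rejuvenation-percentage statistic with
## per-tissue and grand-average summaries.

#' Pearson correlation
#'
#' Standard product-moment correlation; errors on constant input rather
#' than returning `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Median absolute error
#'
#' @param pred,truth Numeric vectors of equal length (years for clocks).
#' @return Median of `|pred - truth|`.
#' @export
median_abs_error <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length", call. = FALSE)
  }
  if (length(pred) < 1) stop("need at least one observation", call. = FALSE)
  stats::median(abs(pred - truth))
}

#' Epigenetic age acceleration
#'
#' The default (difference) definition is DNAm age minus chronological age.
#' The residual mode instead reports the residuals of DNAm age regressed on
#' chronological age (orthogonal to age by construction) in a separately
#' labelled column.
#'
#' @param predictions Tibble with `dnam_age` and `age` columns (as returned
#'   by [predict_age()]).
#' @param mode `"difference"` (default) or `"residual"`.
#' @return The input tibble with `age_acceleration` (difference mode) or
#'   `age_acceleration_residual` (residual mode) filled.
#' @export
age_acceleration <- function(predictions, mode = c("difference", "residual")) {
  mode <- match.arg(mode)
  if (anyNA(predictions$age)) stop("chronological ages required", call. = FALSE)
  if (mode == "difference") {
    dplyr::mutate(predictions, age_acceleration = dnam_age - age)
  } else {
    fit <- stats::lm(dnam_age ~ age, data = predictions)
    dplyr::mutate(predictions,
                  age_acceleration_residual = unname(stats::resid(fit)))
  }
}

#' Group comparison statistics
#'
#' One-way ANOVA across all groups, the classical equal-variance Student
#' t-test restricted to the old-control vs old-treated pair (Welch's form
#' behind `welch = TRUE`), and the two-sided Kruskal-Wallis rank test
#' across all groups.
#'
#' @param data Data frame with the value and group columns.
#' @param value,group Column names (strings) of the per-sample statistic
#'   and the group label.
#' @param control,treated Group labels entering the two-group t-test.
#' @param welch Use Welch's unequal-variance t-test instead of Student's.
#' @return A `group_comparison` object: `$groups` tibble (label, n, mean,
#'   se), `$anova_p`, `$t_p`, `$t_statistic`, `$kruskal_p`, `$kruskal_h`.
#' @export
group_stats <- function(data, value = "value", group = "group",
                        control = "old_control", treated = "old_treated",
                        welch = FALSE) {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("each group needs at least 2 observations",
                              call. = FALSE)
  groups <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(v = v, g = g), g),
    n = dplyr::n(), mean = mean(v), se = stats::sd(v) / sqrt(dplyr::n()),
    .groups = "drop")
  names(groups)[1] <- "group"
  anova_p <- summary(stats::aov(v ~ g))[[1]][["Pr(>F)"]][1]
  kw <- stats::kruskal.test(v, g)
  t_p <- NA_real_; t_stat <- NA_real_
  if (all(c(control, treated) %in% levels(g))) {
    tt <- stats::t.test(v[g == control], v[g == treated],
                        var.equal = !welch)
    t_p <- tt$p.value
    t_stat <- unname(tt$statistic)
  }
  structure(
    list(groups = groups, anova_p = anova_p, t_p = t_p, t_statistic = t_stat,
         kruskal_p = kw$p.value, kruskal_h = unname(kw$statistic),
         welch = welch),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$groups)
  cat(sprintf("ANOVA p = %.4g; t-test p = %.4g; Kruskal-Wallis p = %.4g\n",
              x$anova_p, x$t_p, x$kruskal_p))
  invisible(x)
}

#' Rejuvenation percentage
#'
#' The fraction of the old-control mean epigenetic age removed by the
#' treatment, times 100: `100 * (old - treated) / old`. Values above 50
#' mean the treatment more than halved the epigenetic age. Scale-invariant
#' in the two means.
#'
#' @param mean_old_control,mean_old_treated Mean DNAm ages in years
#'   (old-control must be positive). Vectorized.
#' @return Rejuvenation percentage(s).
#' @export
rejuvenation_percent <- function(mean_old_control, mean_old_treated) {
  if (any(mean_old_control <= 0)) {
    stop("mean old-control epigenetic age must be positive", call. = FALSE)
  }
  100 * (mean_old_control - mean_old_treated) / mean_old_control
}

#' Gap-closure rejuvenation percentage (secondary definition)
#'
#' `100 * (old - treated) / (old - young)`: the fraction of the old-young
#' epigenetic age gap closed by the treatment. Reported alongside the
#' primary statistic, never in its place.
#'
#' @param mean_old_control,mean_old_treated,mean_young Mean DNAm ages.
#' @return Gap-closure percentage(s).
#' @export
rejuvenation_percent_gap_closure <- function(mean_old_control,
                                             mean_old_treated, mean_young) {
  gap <- mean_old_control - mean_young
  if (any(gap <= 0)) stop("old-control mean must exceed young mean", call. = FALSE)
  100 * (mean_old_control - mean_old_treated) / gap
}

#' Summarize rejuvenation across tissues and clocks
#'
#' Expects pooled per-sample predictions for a three-arm study, one row per
#' sample per clock, and computes per tissue x clock group means, the
#' rejuvenation percentage (and its gap-closure variant), per-tissue means
#' across clocks (both orders: mean of per-clock percentages, and the
#' percentage of clock-averaged means) and the unweighted grand mean across
#' tissues.
#'
#' @param predictions Tibble with columns `tissue`, `clock`, `group`,
#'   `dnam_age`; groups must include `young_control`, `old_control` and
#'   `old_treated` in every tissue.
#' @return A `rejuvenation_report`: `$by_clock` tibble, `$by_tissue`
#'   tibble, `$grand_mean` (percent), `$grand_mean_of_averaged` (percent).
#' @export
summarize_rejuvenation <- function(predictions) {
  needed <- c("tissue", "clock", "group", "dnam_age")
  missing_cols <- setdiff(needed, names(predictions))
  if (length(missing_cols) > 0) {
    stop("predictions lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(predictions, tissue, clock, group),
                     mean_age = mean(dnam_age), .groups = "drop"),
    names_from = group, values_from = mean_age)
  need_groups <- c("young_control", "old_control", "old_treated")
  if (!all(need_groups %in% names(wide)) ||
      anyNA(wide[need_groups])) {
    stop("every tissue needs young_control, old_control and old_treated arms",
         call. = FALSE)
  }
  by_clock <- dplyr::transmute(
    wide, tissue, clock,
    mean_age_young = young_control,
    mean_age_old_control = old_control,
    mean_age_old_treated = old_treated,
    rejuvenation_pct = rejuvenation_percent(old_control, old_treated),
    rejuvenation_pct_gap_closure = rejuvenation_percent_gap_closure(
      old_control, old_treated, young_control))
  by_tissue <- dplyr::summarise(
    dplyr::group_by(by_clock, tissue),
    n_clocks = dplyr::n(),
    # mean of the per-clock percentages (primary order)
    rejuvenation_pct = mean(rejuvenation_pct),
    # percentage of the clock-averaged group means (alternative order)
    rejuvenation_pct_of_averaged = rejuvenation_percent(
      mean(mean_age_old_control), mean(mean_age_old_treated)),
    .groups = "drop")
  structure(
    list(by_clock = by_clock, by_tissue = by_tissue,
         grand_mean = mean(by_tissue$rejuvenation_pct),
         grand_mean_of_averaged = mean(by_tissue$rejuvenation_pct_of_averaged)),
    class = "rejuvenation_report")
}

#' @export
print.rejuvenation_report <- function(x, ...) {
  print(x$by_tissue)
  cat(sprintf("grand average rejuvenation across %d tissues: %.2f%%\n",
              nrow(x$by_tissue), x$grand_mean))
  invisible(x)
}

#' Write a rejuvenation report
#'
#' Emits the per tissue x clock TSV and a JSON summary with per-tissue and
#' grand means.
#'
#' @param report A `rejuvenation_report`.
#' @param tsv_path,json_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_rejuvenation_report <- function(report, tsv_path, json_path) {
  readr::write_tsv(report$by_clock, tsv_path)
  jsonlite::write_json(
    list(by_tissue = report$by_tissue, grand_mean = report$grand_mean,
         grand_mean_of_averaged = report$grand_mean_of_averaged),
    json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(tsv = tsv_path, json = json_path))
}
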