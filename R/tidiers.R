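## broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a clock model
#'
#' One row per model term (intercept first), as a coefficient table.
#'
#' @param x A `clock_model`.
#' @param ... Unused.
#' @return Tibble `term, estimate`.
#' @method tidy clock_model
#' @export
tidy.clock_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$weights)),
                 estimate = c(x$intercept, unname(x$weights)))
}

#' One-row summary of a clock model
#'
#' @param x A `clock_model`.
#' @param ... Unused.
#' @return Tibble with probe count, lambda, alpha, transform and training n.
#' @method glance clock_model
#' @export
glance.clock_model <- function(x, ...) {
  tibble::tibble(
    n_probes_selected = length(x$weights),
    lambda = x$lambda,
    alpha = x$training_meta$alpha,
    transform = x$transform$kind,
    n_training_samples = x$training_meta$n_training_samples)
}

#' Per-sample held-out predictions of a cross-validation run
#'
#' @param x A `clock_cv`.
#' @param ... Unused.
#' @return The held-out prediction tibble (with fold assignments).
#' @method tidy clock_cv
#' @export
tidy.clock_cv <- function(x, ...) x$predictions

#' One-row summary of a cross-validation run
#'
#' @param x A `clock_cv`.
#' @param ... Unused.
#' @return Tibble `scheme, n, pearson_r, median_abs_error`.
#' @method glance clock_cv
#' @export
glance.clock_cv <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, n = x$n, pearson_r = x$pearson_r,
                 median_abs_error = x$median_abs_error)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Per-group tibble `group, n, mean, se`.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$groups

#' One-row summary of a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Tibble `anova_p, t_statistic, t_p, kruskal_h, kruskal_p`.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(anova_p = x$anova_p, t_statistic = x$t_statistic,
                 t_p = x$t_p, kruskal_h = x$kruskal_h,
                 kruskal_p = x$kruskal_p)
}

#' Tidy a rejuvenation report
#'
#' @param x A `rejuvenation_report`.
#' @param ... Unused.
#' @return The per tissue x clock tibble.
#' @method tidy rejuvenation_report
#' @export
tidy.rejuvenation_report <- function(x, ...) x$by_clock

#' One-row summary of a rejuvenation report
#'
#' @param x A `rejuvenation_report`.
#' @param ... Unused.
#' @return Tibble `n_tissues, grand_mean, grand_mean_of_averaged`.
#' @method glance rejuvenation_report
#' @export
glance.rejuvenation_report <- function(x, ...) {
  tibble::tibble(n_tissues = nrow(x$by_tissue), grand_mean = x$grand_mean,
                 grand_mean_of_averaged = x$grand_mean_of_averaged)
}

#' Scatter plot of held-out DNAm age against chronological age
#'
#' @param object A `clock_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot clock_cv
#' @export
autoplot.clock_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = age, y = dnam_age, colour = tissue)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "chronological age (years)", y = "DNAm age (years)",
      title = sprintf("%s: R = %.2f, MAE = %.2f years", object$scheme,
                      object$pearson_r, object$median_abs_error)) +
    ggplot2::theme_minimal()
}

#' Per-tissue rejuvenation bar chart
#'
#' @param object A `rejuvenation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rejuvenation_report
#' @export
autoplot.rejuvenation_report <- function(object, ...) {
  ggplot2::ggplot(object$by_tissue,
                  ggplot2::aes(x = tissue, y = rejuvenation_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$grand_mean, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "rejuvenation (%)",
                  title = sprintf("grand average %.1f%%", object$grand_mean)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of an EWAS contrast
#'
#' @param results Tibble from [apply_contrast()].
#' @return A ggplot.
#' @export
plot_ewas_volcano <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = estimate, y = -log10(p),
                               colour = significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "contrast estimate (beta units)",
                  y = expression(-log[10](p)),
                  title = unique(results$contrast)) +
    ggplot2::theme_minimal()
}
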