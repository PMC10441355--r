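## Per-CpG EWAS of age and treatment effects.
##
## The model is per-probe ordinary least squares of (beta or M-)values on a
## design of condition indicators (no global intercept), plate and array-
## column indicators, plus k factors of unwanted variation estimated from
## negative-control probes. Residual variances are moderated toward a
## common prior by empirical Bayes (the scaled inverse-chi-square /
## F-distribution moment-matching of the moderated-t framework), contrasts
## of interest are the treatment effect in age-matched old animals
## ("Elixir": old_treated - old_control) and the aging effect
## ("Age": old_control - young_control), and p-values are Benjamini-
## Hochberg adjusted within each contrast.

#' Build the EWAS design matrix
#'
#' Condition indicators without a global intercept (`~ 0 + group`), plus
#' plate and array-column indicators and any RUV factor columns. Aliased
#' (rank-deficient) columns are dropped with a message.
#'
#' @param annotation Sample annotation tibble (row order = beta columns).
#' @param ruv Optional matrix of RUV factors (samples x k).
#' @param covariates Character vector of annotation columns entering as
#'   factors after the condition block.
#' @return Numeric design matrix with full column rank.
#' @export
ewas_design <- function(annotation, ruv = NULL,
                        covariates = c("batch_plate", "batch_column")) {
  ann <- validate_sample_annotation(annotation)
  parts <- list(stats::model.matrix(~ 0 + factor(ann$group)))
  colnames(parts[[1]]) <- sub("factor\\(ann\\$group\\)", "group_",
                              colnames(parts[[1]]))
  for (cv in covariates) {
    f <- factor(ann[[cv]])
    if (nlevels(f) > 1) {
      mm <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, "_", levels(f)[-1])
      parts <- c(parts, list(mm))
    }
  }
  if (!is.null(ruv) && ncol(ruv) > 0) {
    colnames(ruv) <- paste0("ruv_", seq_len(ncol(ruv)))
    parts <- c(parts, list(ruv))
  }
  X <- do.call(cbind, parts)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    message("dropping aliased design column(s): ",
            paste(drop_cols, collapse = ", "))
    X <- X[, setdiff(colnames(X), drop_cols), drop = FALSE]
  }
  X
}

#' Select empirical negative-control probes
#'
#' Ranks probes by their absolute marginal correlation with age and by
#' their between-group variance fraction across conditions, sums the two
#' ranks, and returns the `n_controls` probes with the smallest rank-sum —
#' the probes least associated with either signal. Ties resolve by probe
#' id lexicographic order, so the selection is deterministic.
#'
#' @param beta Complete beta matrix.
#' @param annotation Sample annotation.
#' @param n_controls Number of control probes to return (default 500).
#' @return Character vector of probe ids.
#' @export
select_control_probes <- function(beta, annotation, n_controls = 500) {
  ann <- align_annotation(beta, annotation)
  if (n_controls >= nrow(beta)) {
    stop("n_controls must be below the total probe count", call. = FALSE)
  }
  age_assoc <- abs(suppressWarnings(stats::cor(t(beta), ann$age)))[, 1]
  age_assoc[is.na(age_assoc)] <- 0
  g <- factor(ann$group)
  if (nlevels(g) > 1) {
    centered <- beta - rowMeans(beta)
    sst <- rowSums(centered^2)
    group_means <- vapply(levels(g), function(l) {
      rowMeans(beta[, g == l, drop = FALSE])
    }, numeric(nrow(beta)))
    counts <- as.numeric(table(g)[colnames(group_means)])
    ssb <- rowSums(sweep((group_means - rowMeans(beta))^2, 2, counts, `*`))
    cond_assoc <- ifelse(sst > 0, ssb / sst, 0)
  } else {
    cond_assoc <- rep(0, nrow(beta))
  }
  # rank with deterministic lexicographic tie-break: sort keys (value, id)
  rank_by <- function(v) {
    rank_pos <- order(v, rownames(beta))
    r <- integer(length(v)); r[rank_pos] <- seq_along(v); r
  }
  total <- rank_by(age_assoc) + rank_by(cond_assoc)
  sel_pos <- order(total, rownames(beta))[seq_len(n_controls)]
  rownames(beta)[sel_pos]
}

#' Estimate factors of unwanted variation from control probes
#'
#' Singular-value decomposition of the row-centred control-probe submatrix;
#' the top-k right singular vectors (sample loadings) are returned as an
#' orthonormal samples x k matrix.
#'
#' @param beta Complete beta matrix.
#' @param control_probes Probe ids treated as negative controls.
#' @param k Number of factors (default 2; `k = 0` returns a zero-column
#'   matrix).
#' @return Samples x k matrix with orthonormal columns, class `ruv_factors`.
#' @export
estimate_ruv_factors <- function(beta, control_probes, k = 2) {
  if (k == 0) {
    out <- matrix(numeric(0), nrow = ncol(beta), ncol = 0)
    rownames(out) <- colnames(beta)
    return(structure(out, control_probes = character(0), class = c("ruv_factors", "matrix")))
  }
  missing <- setdiff(control_probes, rownames(beta))
  if (length(missing) > 0) {
    stop("control probes absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- beta[control_probes, , drop = FALSE]
  x <- x - rowMeans(x)
  sv <- svd(x, nu = 0, nv = k)
  if (k > length(sv$d) || sv$d[k] < 1e-12) {
    stop("k exceeds the rank of the centred control-probe matrix", call. = FALSE)
  }
  v <- sv$v[, seq_len(k), drop = FALSE]
  rownames(v) <- colnames(beta)
  colnames(v) <- paste0("ruv_", seq_len(k))
  structure(v, control_probes = control_probes, class = c("ruv_factors", "matrix"))
}

#' Fit per-probe least-squares models
#'
#' One ordinary least-squares fit per probe against a shared design:
#' coefficient matrix, residual variances `s2` and the common residual
#' degrees of freedom `n - rank(design)`.
#'
#' @param beta Complete matrix of responses (betas or M-values), probes x
#'   samples; column order must match the design rows.
#' @param design Full-rank design matrix from [ewas_design()].
#' @return An `ewas_fit`: `coefficients` (probes x terms), `s2`, `df`,
#'   `xtx_inv`, `design`.
#' @export
fit_probe_models <- function(beta, design) {
  if (ncol(beta) != nrow(design)) {
    stop("design rows must match beta columns", call. = FALSE)
  }
  if (anyNA(beta)) stop("impute the matrix before model fitting", call. = FALSE)
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    aliased <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
    stop("design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- lm.fit(design, t(beta))
  coefs <- t(as.matrix(fit$coefficients))
  res <- as.matrix(fit$residuals)
  dimnames(coefs) <- list(rownames(beta), colnames(design))
  df <- nrow(design) - qrX$rank
  s2 <- if (df > 0) colSums(res^2) / df else rep(NA_real_, ncol(res))
  xtx_inv <- chol2inv(qr.R(qrX))
  dimnames(xtx_inv) <- list(colnames(design), colnames(design))
  structure(
    list(coefficients = coefs, s2 = unname(s2), df = df, xtx_inv = xtx_inv,
         design = design, probe_ids = rownames(beta),
         d0 = NULL, s0_2 = NULL),
    class = "ewas_fit")
}

# Invert trigamma(x) = y by Newton iteration (monotone decreasing).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of residual variances
#'
#' Estimates prior degrees of freedom `d0` and prior variance `s0_2` by
#' matching the moments of `log(s2)` to a scaled F distribution, then
#' forms the moderated variances `s2_tilde = (d0*s0_2 + d*s2) / (d0 + d)`.
#' When the observed variances show no excess dispersion over the
#' chi-square sampling noise, `d0` is infinite and every moderated
#' variance equals the common prior. Probes with `s2 = 0` are offset by
#' the smallest positive `s2` times 1e-8 before taking logs.
#'
#' @param fit An `ewas_fit`.
#' @return The fit with `d0`, `s0_2` and `s2_tilde` filled in.
#' @export
ebayes_moderate <- function(fit) {
  stopifnot(inherits(fit, "ewas_fit"))
  s2 <- fit$s2
  d <- fit$df
  if (length(s2) < 2) stop("moderation needs at least 2 probes", call. = FALSE)
  if (d <= 0) stop("no residual degrees of freedom", call. = FALSE)
  if (all(s2 == 0)) stop("all residual variances are zero", call. = FALSE)
  pos_min <- min(s2[s2 > 0])
  s2_work <- ifelse(s2 == 0, pos_min * 1e-8, s2)
  z <- log(s2_work)
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  n <- length(e)
  excess <- mean((e - ebar)^2) * n / (n - 1) - trigamma(d / 2)
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(ebar)
  }
  s2_tilde <- if (is.infinite(d0)) rep(s0_2, n) else (d0 * s0_2 + d * s2) / (d0 + d)
  fit$d0 <- d0
  fit$s0_2 <- s0_2
  fit$s2_tilde <- s2_tilde
  fit
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Apply a contrast to an EWAS fit
#'
#' Computes `estimate = c' beta_hat` per probe with moderated (default) or
#' ordinary t-statistics, two-sided p-values on `d0 + d` (or `d`) degrees
#' of freedom, and BH-adjusted q-values within the contrast.
#'
#' @param fit An `ewas_fit` (pass through [ebayes_moderate()] first unless
#'   `moderated = FALSE`).
#' @param contrast Named numeric vector over design columns (unnamed
#'   columns get weight 0), e.g.
#'   `c(group_old_treated = 1, group_old_control = -1)`.
#' @param name Contrast label carried into the result.
#' @param moderated Use moderated variances (default `TRUE`).
#' @param fdr Significance threshold on q (default 0.05).
#' @return Tibble `probe_id, contrast, estimate, t, p, q, significant`.
#' @export
apply_contrast <- function(fit, contrast, name = "contrast",
                           moderated = TRUE, fdr = 0.05) {
  stopifnot(inherits(fit, "ewas_fit"))
  cols <- colnames(fit$design)
  unknown <- setdiff(names(contrast), cols)
  if (length(unknown) > 0) {
    stop("contrast names not in design: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cvec <- stats::setNames(numeric(length(cols)), cols)
  for (i in seq_along(contrast)) {  # accumulate, so repeated names cancel
    cvec[names(contrast)[i]] <- cvec[names(contrast)[i]] + contrast[[i]]
  }
  est <- drop(fit$coefficients %*% cvec)
  c_var_unit <- drop(t(cvec) %*% fit$xtx_inv %*% cvec)
  if (moderated) {
    if (is.null(fit$s2_tilde)) fit <- ebayes_moderate(fit)
    var_probe <- fit$s2_tilde
    df_t <- fit$d0 + fit$df
  } else {
    var_probe <- fit$s2
    df_t <- fit$df
  }
  se <- sqrt(var_probe * c_var_unit)
  tstat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
  p <- if (is.infinite(df_t)) {
    2 * stats::pnorm(-abs(tstat))
  } else {
    2 * stats::pt(-abs(tstat), df = df_t)
  }
  q <- bh_adjust(p)
  tibble::tibble(
    probe_id = fit$probe_ids, contrast = name, estimate = unname(est),
    t = unname(tstat), p = unname(p), q = unname(q),
    significant = q < fdr)
}

#' Reversal summary of age and treatment contrasts
#'
#' Among probes significant for the Age contrast at the FDR threshold,
#' counts how many have a treatment estimate of opposite sign, split by
#' direction of the aging change (age-gain vs age-loss). An empty
#' significant set is reported with zero counts, not an error.
#'
#' @param age_results,treatment_results Tibbles from [apply_contrast()]
#'   over the same probe universe.
#' @param fdr FDR threshold applied to the Age contrast (default 0.05).
#' @return List with `n_age_significant`, per-direction counts/proportions,
#'   and the overall `reversal_proportion`.
#' @export
reversal_summary <- function(age_results, treatment_results, fdr = 0.05) {
  if (!setequal(age_results$probe_id, treatment_results$probe_id)) {
    stop("the two contrasts cover different probe universes", call. = FALSE)
  }
  tr <- treatment_results[match(age_results$probe_id,
                                treatment_results$probe_id), ]
  sig <- age_results$q < fdr
  if (!any(sig)) {
    return(list(n_age_significant = 0L, n_reversed = 0L,
                reversal_proportion = NA_real_,
                gain = list(n = 0L, reversed = 0L, proportion = NA_real_),
                loss = list(n = 0L, reversed = 0L, proportion = NA_real_)))
  }
  age_est <- age_results$estimate[sig]
  tr_est <- tr$estimate[sig]
  reversed <- sign(tr_est) == -sign(age_est) & age_est != 0
  gain <- age_est > 0
  prop <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  list(
    n_age_significant = sum(sig),
    n_reversed = sum(reversed),
    reversal_proportion = mean(reversed),
    gain = list(n = sum(gain), reversed = sum(reversed[gain]),
                proportion = prop(reversed[gain])),
    loss = list(n = sum(!gain), reversed = sum(reversed[!gain]),
                proportion = prop(reversed[!gain]))
  )
}

#' Run the full EWAS stage
#'
#' Convenience wrapper: select empirical control probes, estimate `k` RUV
#' factors, build the design, fit per-probe models, moderate, and apply the
#' Age (old_control - young_control) and Elixir (old_treated - old_control)
#' contrasts.
#'
#' @param beta Complete beta matrix.
#' @param annotation Three-arm sample annotation.
#' @param k RUV factors (default 2).
#' @param n_controls Empirical negative controls (default 500).
#' @param fdr FDR threshold (default 0.05).
#' @param use_m_values Model `log2(beta / (1 - beta))` instead of betas.
#' @return List with `age`, `elixir` result tibbles, the `reversal`
#'   summary, `control_probes`, `ruv`, `fit`.
#' @export
run_ewas <- function(beta, annotation, k = 2, n_controls = 500, fdr = 0.05,
                     use_m_values = FALSE) {
  ann <- align_annotation(beta, annotation)
  controls <- select_control_probes(beta, ann, n_controls = n_controls)
  ruv <- estimate_ruv_factors(beta, controls, k = k)
  design <- ewas_design(ann, ruv = if (k > 0) unclass(ruv) else NULL)
  y <- beta
  if (use_m_values) {
    eps <- 1e-6
    y <- log2(pmin(pmax(beta, eps), 1 - eps) /
                (1 - pmin(pmax(beta, eps), 1 - eps)))
  }
  fit <- ebayes_moderate(fit_probe_models(y, design))
  age <- apply_contrast(fit, c(group_old_control = 1, group_young_control = -1),
                        name = "Age", fdr = fdr)
  elixir <- apply_contrast(fit, c(group_old_treated = 1, group_old_control = -1),
                           name = "Elixir", fdr = fdr)
  list(age = age, elixir = elixir,
       reversal = reversal_summary(age, elixir, fdr = fdr),
       control_probes = controls, ruv = ruv, fit = fit)
}
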