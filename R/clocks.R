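## Penalized-regression epigenetic clocks.
##
## A clock is an elastic-net linear model (mixing parameter fixed at 0.5,
## midway between ridge and lasso) of transformed age on probe betas. The
## penalty strength is chosen by internal 10-fold cross-validation
## minimizing mean squared error; ties are broken toward the largest
## (sparsest) lambda. Two response transforms are supported: identity
## (years) and relative age (age divided by the species maximum lifespan,
## rat 3.8 years, human 122.5 years), which places species with very
## different lifespans on a common [0, 1] scale.

#' Age transform for clock responses
#'
#' @param kind `"identity"` (model age in years) or `"relative"` (model
#'   age / species maximum lifespan).
#' @param max_lifespan Named vector of species maximum lifespans in years.
#' @return An `age_transform` object.
#' @export
age_transform <- function(kind = c("identity", "relative"),
                          max_lifespan = MAX_LIFESPAN_YEARS) {
  kind <- match.arg(kind)
  if (is.null(names(max_lifespan)) || any(max_lifespan <= 0)) {
    stop("max_lifespan must be a named vector of positive years", call. = FALSE)
  }
  structure(list(kind = kind, max_lifespan = max_lifespan),
            class = "age_transform")
}

lifespan_of <- function(transform, species) {
  unknown <- setdiff(unique(species), names(transform$max_lifespan))
  if (length(unknown) > 0) {
    stop("no maximum lifespan configured for species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unname(transform$max_lifespan[species])
}

#' Relative age of a sample
#'
#' Relative age is chronological age divided by the species maximum
#' lifespan (rat 3.8 years, human 122.5 years by default). Values above 1
#' (ages beyond the nominal maximum) are permitted with a warning.
#'
#' @param age Age(s) in years, non-negative.
#' @param species Species name(s), recycled against `age`.
#' @param max_lifespan Named vector of species maximum lifespans in years.
#' @return Relative age(s) in `[0, 1]` (or slightly above, with a warning).
#' @export
relative_age <- function(age, species, max_lifespan = MAX_LIFESPAN_YEARS) {
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  tr <- age_transform("relative", max_lifespan)
  out <- age / lifespan_of(tr, species)
  if (any(out > 1)) {
    warning("relative age above 1: age exceeds the configured maximum lifespan")
  }
  out
}

transform_age <- function(transform, age, species) {
  switch(transform$kind,
    identity = age,
    relative = age / lifespan_of(transform, species))
}

invert_age <- function(transform, value, species) {
  switch(transform$kind,
    identity = value,
    relative = value * lifespan_of(transform, species))
}

align_annotation <- function(beta, annotation) {
  annotation <- validate_sample_annotation(annotation)
  missing <- setdiff(colnames(beta), annotation$sample_id)
  if (length(missing) > 0) {
    stop("samples absent from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  annotation[match(colnames(beta), annotation$sample_id), ]
}

#' Fit an epigenetic clock by elastic-net regression
#'
#' Regresses transformed age on probe betas with `glmnet` (alpha fixed at
#' 0.5); the penalty is chosen by internal k-fold cross-validation (k = 10
#' by default, reduced to the sample count for very small panels)
#' minimizing mean squared error. A constant response is handled as a
#' degenerate fit: zero weights and intercept equal to the transformed
#' common age.
#'
#' @param beta Complete (imputed) beta matrix, probes x samples.
#' @param annotation Sample annotation tibble covering all columns of `beta`.
#' @param transform An [age_transform()].
#' @param tissues Optional character vector restricting training to these
#'   tissues (`NULL` trains the pan-tissue clock).
#' @param nfolds Folds for internal lambda selection (default 10).
#' @param seed Seed controlling fold assignment.
#' @return A `clock_model` object.
#' @export
fit_clock <- function(beta, annotation, transform = age_transform("identity"),
                      tissues = NULL, nfolds = 10, seed = 1) {
  stopifnot(inherits(transform, "age_transform"))
  ann <- align_annotation(beta, annotation)
  if (!is.null(tissues)) {
    keep <- ann$tissue %in% tissues
    if (!any(keep)) stop("no samples left after tissue filtering", call. = FALSE)
    beta <- beta[, keep, drop = FALSE]
    ann <- ann[keep, ]
  }
  if (anyNA(beta)) stop("beta matrix must be imputed before fitting", call. = FALSE)
  n <- ncol(beta)
  if (n < 2) stop("need at least 2 training samples", call. = FALSE)
  y <- transform_age(transform, ann$age, ann$species)
  meta <- list(tissues = tissues %||% "all",
               species = sort(unique(ann$species)),
               alpha = 0.5, n_training_samples = n, seed = seed,
               standardized = FALSE)
  if (stats::sd(y) == 0) {
    model <- structure(
      list(weights = stats::setNames(numeric(0), character(0)),
           intercept = y[1], transform = transform,
           lambda = NA_real_, training_meta = meta,
           probe_universe = rownames(beta)),
      class = "clock_model")
    return(model)
  }
  k <- min(nfolds, n)
  if (k < 3) stop("internal lambda selection needs at least 3 samples", call. = FALSE)
  x <- t(beta)
  cvfit <- local_seed(seed, {
    foldid <- sample(rep_len(seq_len(k), n))
    withCallingHandlers(
      glmnet::cv.glmnet(x, y, alpha = 0.5, foldid = foldid,
                        standardize = FALSE, family = "gaussian"),
      # small panels force per-observation CV errors; not actionable here
      warning = function(w) {
        if (grepl("grouped=FALSE enforced", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  })
  # largest lambda among those within numerical tie of the minimum CV error
  cvm <- cvfit$cvm
  ties <- which(cvm <= min(cvm) * (1 + 1e-12))
  lambda <- max(cvfit$lambda[ties])
  co <- stats::coef(cvfit, s = lambda)
  w <- as.numeric(co)[-1]
  names(w) <- rownames(co)[-1]
  w <- w[w != 0]
  structure(
    list(weights = w, intercept = as.numeric(co)[1], transform = transform,
         lambda = lambda, training_meta = meta,
         probe_universe = rownames(beta)),
    class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %s transform, %d nonzero probes, lambda = %s\n",
              x$transform$kind, length(x$weights),
              format(x$lambda, digits = 4)))
  cat(sprintf("  trained on %d samples (tissues: %s)\n",
              x$training_meta$n_training_samples,
              paste(x$training_meta$tissues, collapse = ", ")))
  invisible(x)
}

#' Predict DNA methylation age
#'
#' Computes the linear score `intercept + sum(weight * beta)` per sample
#' and back-transforms it to years (for the relative transform: score
#' times the species maximum lifespan). Negative ages are reported as-is.
#'
#' @param clock A `clock_model`.
#' @param beta Beta matrix containing every clock probe.
#' @param annotation Annotation covering the samples (species is needed for
#'   the relative transform; chronological age enables age acceleration).
#' @return Tibble `sample_id, species, tissue, group, age, dnam_age,
#'   age_acceleration`.
#' @export
predict_age <- function(clock, beta, annotation) {
  stopifnot(inherits(clock, "clock_model"))
  ann <- align_annotation(beta, annotation)
  need <- names(clock$weights)
  missing <- setdiff(need, rownames(beta))
  if (length(missing) > 0) {
    stop("clock probes missing from the matrix: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  if (anyNA(beta[need, , drop = FALSE])) {
    stop("beta matrix has missing values at clock probes; impute first",
         call. = FALSE)
  }
  score <- if (length(need) == 0) {
    rep(clock$intercept, ncol(beta))
  } else {
    drop(crossprod(beta[need, , drop = FALSE], clock$weights)) + clock$intercept
  }
  dnam_age <- invert_age(clock$transform, score, ann$species)
  tibble::tibble(
    sample_id = ann$sample_id,
    species = ann$species,
    tissue = ann$tissue,
    group = ann$group,
    age = ann$age,
    dnam_age = unname(dnam_age),
    age_acceleration = unname(dnam_age) - ann$age
  )
}

#' Cross-validate a clock
#'
#' Repeats the full [fit_clock()] procedure — including internal lambda
#' selection — with each unit held out (leave-one-out) or with k-fold
#' partitioning, then pools the held-out predictions and reports their
#' Pearson correlation with chronological age and the median absolute
#' error in years. The held-out samples never influence lambda selection.
#'
#' @param beta Complete beta matrix.
#' @param annotation Sample annotation.
#' @param transform An [age_transform()].
#' @param scheme `"loocv"` or an integer k for k-fold cross-validation.
#' @param tissues Optional tissue restriction (applied before folding).
#' @param nfolds Folds for the internal lambda selection in each refit.
#' @param seed Seed for fold assignment.
#' @return A `clock_cv` object: `predictions` tibble (with `fold`),
#'   `pearson_r`, `median_abs_error`, `scheme`, `seed`.
#' @export
cross_validate_clock <- function(beta, annotation,
                                 transform = age_transform("identity"),
                                 scheme = "loocv", tissues = NULL,
                                 nfolds = 10, seed = 1) {
  ann <- align_annotation(beta, annotation)
  if (!is.null(tissues)) {
    keep <- ann$tissue %in% tissues
    beta <- beta[, keep, drop = FALSE]
    ann <- ann[keep, ]
  }
  n <- ncol(beta)
  if (n < 3) stop("cross-validation needs at least 3 samples", call. = FALSE)
  if (identical(scheme, "loocv")) {
    fold_of <- seq_len(n)
    scheme_label <- "loocv"
  } else {
    k <- as.integer(scheme)
    if (is.na(k) || k < 2 || k > n) {
      stop("k-fold scheme needs 2 <= k <= n", call. = FALSE)
    }
    fold_of <- local_seed(seed, sample(rep_len(seq_len(k), n)))
    scheme_label <- paste0(k, "-fold")
  }
  preds <- vector("list", max(fold_of))
  for (f in sort(unique(fold_of))) {
    hold <- fold_of == f
    clock_f <- fit_clock(beta[, !hold, drop = FALSE], ann[!hold, ],
                         transform = transform, nfolds = nfolds,
                         seed = seed + f)
    p <- predict_age(clock_f, beta[, hold, drop = FALSE], ann[hold, ])
    p$fold <- f
    preds[[f]] <- p
  }
  predictions <- dplyr::bind_rows(preds)
  predictions <- predictions[match(ann$sample_id, predictions$sample_id), ]
  structure(
    list(predictions = predictions,
         pearson_r = pearson_r(predictions$dnam_age, predictions$age),
         median_abs_error = median_abs_error(predictions$dnam_age,
                                             predictions$age),
         scheme = scheme_label, n = n, seed = seed),
    class = "clock_cv")
}

#' @export
print.clock_cv <- function(x, ...) {
  cat(sprintf("<clock_cv> %s over %d samples: R = %.3f, MAE = %.3f years\n",
              x$scheme, x$n, x$pearson_r, x$median_abs_error))
  invisible(x)
}
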