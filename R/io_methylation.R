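## Reading, writing and validating methylation beta matrices and sample
## annotation sheets, plus dataset alignment and correlation-based outlier QC.
##
## A beta matrix is a plain numeric matrix with probes in rows and samples in
## columns (row/column names carry the identifiers); values are methylation
## fractions in [0, 1], NA marks a missing call. Sample annotations are
## tibbles with one row per sample.

ANNOTATION_COLUMNS <- c("sample_id", "species", "tissue", "age", "sex",
                        "batch_plate", "batch_column", "group", "subject_id",
                        "timepoint")
REQUIRED_ANNOTATION_COLUMNS <- c("sample_id", "species", "tissue", "age")
GROUP_LEVELS <- c("young_control", "old_control", "old_treated", "none")

#' Validate a methylation beta matrix
#'
#' Checks that `m` is a numeric matrix with unique probe and sample
#' identifiers and all non-missing values inside `[0, 1]`. Violations raise
#' errors that name the offending probe and sample.
#'
#' @param m Numeric matrix, probes in rows, samples in columns.
#' @return `m`, invisibly.
#' @export
validate_beta_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("beta matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("beta matrix must carry probe ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate probe ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1]: probe %s, sample %s (value %g)",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                 m[bad[1, 1], bad[1, 2]]),
         call. = FALSE)
  }
  invisible(m)
}

#' Read a beta matrix from TSV
#'
#' The on-disk layout is tab-separated text with a `probe_id` first column
#' and one column per sample (missing cells empty or `NA`). Use
#' `orientation = "samples_in_rows"` for the transposed layout.
#'
#' @param path Path to a TSV file.
#' @param orientation `"probes_in_rows"` (default) or `"samples_in_rows"`.
#' @return Validated numeric matrix, probes in rows.
#' @export
read_beta_matrix <- function(path,
                             orientation = c("probes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2) stop("beta matrix file needs an id column plus data columns",
                         call. = FALSE)
  ids <- df[[1]]
  raw <- as.matrix(df[, -1, drop = FALSE])
  m <- suppressWarnings(array(as.numeric(raw), dim = dim(raw),
                              dimnames = dimnames(raw)))
  unparsed <- is.na(m) & !is.na(raw) & raw != "NA" & raw != ""
  if (any(unparsed)) {
    bad <- which(unparsed, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric beta value '%s' at row id %s, column %s",
                 raw[bad[1], bad[2]], ids[bad[1]], colnames(raw)[bad[2]]),
         call. = FALSE)
  }
  rownames(m) <- ids
  if (orientation == "samples_in_rows") m <- t(m)
  validate_beta_matrix(m)
  m
}

#' Write a beta matrix to TSV
#'
#' @param m Beta matrix (probes in rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path) {
  validate_beta_matrix(m)
  df <- tibble::as_tibble(m, rownames = "probe_id")
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' Count missing entries of a beta matrix
#'
#' @param m Beta matrix.
#' @return Integer count of missing cells.
#' @export
n_missing <- function(m) sum(is.na(m))

#' Read a sample annotation sheet
#'
#' CSV with required columns `sample_id`, `species`, `tissue`, `age` (years);
#' optional columns (`sex`, `batch_plate`, `batch_column`, `group`,
#' `subject_id`, `timepoint`) default to `"unknown"` / `"none"` / `NA`.
#' Ages are always years: week- or month-based ages must be converted by the
#' caller before writing the sheet.
#'
#' @param path Path to a CSV file.
#' @return Tibble with one row per sample and the full annotation schema.
#' @export
read_sample_annotation <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing_cols <- setdiff(REQUIRED_ANNOTATION_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("sample sheet is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  col_or <- function(name, default) {
    if (name %in% names(df)) df[[name]] else default
  }
  validate_sample_annotation(
    tibble::tibble(
      sample_id = df$sample_id,
      species = df$species,
      tissue = df$tissue,
      age = as.numeric(df$age),
      sex = col_or("sex", "unknown"),
      batch_plate = col_or("batch_plate", "unknown"),
      batch_column = col_or("batch_column", "unknown"),
      group = col_or("group", "none"),
      subject_id = col_or("subject_id", df$sample_id),
      timepoint = col_or("timepoint", NA_character_)
    )
  )
}

#' Validate a sample annotation tibble
#'
#' @param ann Tibble with the annotation schema.
#' @return `ann` (with missing optional columns filled), invisibly usable.
#' @export
validate_sample_annotation <- function(ann) {
  missing_cols <- setdiff(REQUIRED_ANNOTATION_COLUMNS, names(ann))
  if (length(missing_cols) > 0) {
    stop("annotation is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(ANNOTATION_COLUMNS, names(ann))) {
    ann[[col]] <- switch(col,
      sex = "unknown", batch_plate = "unknown", batch_column = "unknown",
      group = "none", subject_id = ann$sample_id, timepoint = NA_character_)
  }
  if (anyDuplicated(ann$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(ann$age))) stop("unparseable age values in sample sheet", call. = FALSE)
  if (any(ann$age < 0)) {
    stop("negative age for sample(s): ",
         paste(ann$sample_id[ann$age < 0], collapse = ", "), call. = FALSE)
  }
  bad_group <- setdiff(unique(ann$group), GROUP_LEVELS)
  if (length(bad_group) > 0) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  ann[, ANNOTATION_COLUMNS]
}

#' Write a sample annotation sheet
#' @param ann Annotation tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_annotation <- function(ann, path) {
  ann <- validate_sample_annotation(ann)
  readr::write_csv(ann, path, na = "")
  invisible(path)
}

#' Restrict two beta matrices to their shared probes
#'
#' Both outputs carry the shared probes in the same order (sorted probe id),
#' so that cross-panel analyses line up row-by-row. Swapping the arguments
#' yields the same shared probe set.
#'
#' @param a,b Beta matrices.
#' @return List with elements `a` and `b`, both restricted to shared probes.
#' @export
intersect_probes <- function(a, b) {
  validate_beta_matrix(a)
  validate_beta_matrix(b)
  shared <- sort(intersect(rownames(a), rownames(b)))
  if (length(shared) == 0) stop("no shared probes between the two matrices",
                                call. = FALSE)
  list(a = a[shared, , drop = FALSE], b = b[shared, , drop = FALSE])
}

#' Impute missing beta values by per-probe mean
#'
#' Observed values are left untouched; each missing cell gets the mean of the
#' observed values of its probe. Idempotent. Errors if some probe has no
#' observed value at all.
#'
#' @param m Beta matrix possibly containing `NA`.
#' @return Complete beta matrix.
#' @export
impute_missing <- function(m) {
  validate_beta_matrix(m)
  if (!anyNA(m)) return(m)
  all_missing <- rowSums(!is.na(m)) == 0
  if (any(all_missing)) {
    stop("probe(s) with all values missing: ",
         paste(utils::head(rownames(m)[all_missing], 5), collapse = ", "),
         call. = FALSE)
  }
  means <- rowMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- means[idx[, 1]]
  m
}

#' Flag outlying samples by mean inter-sample correlation
#'
#' Computes, for each sample, the mean pairwise Pearson correlation to every
#' other sample and flags samples falling below `threshold`. This is a
#' deterministic proxy for dendrogram-based outlier exclusion; the
#' corresponding average-linkage tree on distance `1 - r` is available via
#' [outlier_dendrogram()]. A constant-valued sample (undefined correlation)
#' is reported with `mean_correlation = NA` and `degenerate = TRUE`.
#'
#' @param m Beta matrix with at least 3 samples.
#' @param threshold Correlation threshold below which a sample is flagged
#'   (default 0.80).
#' @return Tibble `sample_id, mean_correlation, flagged, degenerate`, one row
#'   per sample in the input column order.
#' @export
flag_outliers <- function(m, threshold = 0.8) {
  validate_beta_matrix(m)
  if (ncol(m) < 3) stop("outlier QC needs at least 3 samples", call. = FALSE)
  m <- impute_missing(m)
  degenerate <- apply(m, 2, function(x) stats::sd(x) == 0)
  cc <- suppressWarnings(stats::cor(m))
  diag(cc) <- NA
  mean_cor <- rowMeans(cc, na.rm = TRUE)
  mean_cor[degenerate] <- NA_real_
  tibble::tibble(
    sample_id = colnames(m),
    mean_correlation = unname(mean_cor),
    flagged = !is.na(mean_cor) & mean_cor < threshold,
    degenerate = unname(degenerate)
  )
}

#' Average-linkage sample dendrogram on correlation distance
#'
#' @param m Beta matrix.
#' @return `hclust` object over samples with distance `1 - r`.
#' @export
outlier_dendrogram <- function(m) {
  validate_beta_matrix(m)
  m <- impute_missing(m)
  d <- stats::as.dist(1 - suppressWarnings(stats::cor(m)))
  stats::hclust(d, method = "average")
}

#' Write an outlier report
#' @param report Tibble from [flag_outliers()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_outlier_report <- function(report, path) {
  readr::write_tsv(report[, c("sample_id", "mean_correlation", "flagged")], path)
  invisible(path)
}
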