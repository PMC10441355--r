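## Clock serialization: a CSV coefficient table (the publication format for
## clock releases) plus a JSON sidecar with the transform and training
## metadata. Round-trips are exact at full double precision.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Save a clock to a coefficient file
#'
#' Writes a CSV with header `term,weight` whose first row is the
#' `(Intercept)` followed by one row per nonzero probe weight, and a JSON
#' sidecar (same stem, `.json`) carrying transform kind, species lifespans,
#' alpha, lambda, seed and training metadata.
#'
#' @param clock A `clock_model`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_clock <- function(clock, path) {
  stopifnot(inherits(clock, "clock_model"))
  df <- tibble::tibble(
    term = c("(Intercept)", names(clock$weights)),
    # 17 significant digits: doubles survive the text round-trip bit-exactly
    weight = sprintf("%.17g", c(clock$intercept, unname(clock$weights)))
  )
  readr::write_csv(df, path)
  meta <- list(
    format_version = 1L,
    transform = list(kind = clock$transform$kind,
                     max_lifespan = as.list(clock$transform$max_lifespan)),
    lambda = clock$lambda,
    training_meta = clock$training_meta
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a clock from a coefficient file
#'
#' @param path Path to a CSV written by [save_clock()] (the JSON sidecar
#'   must sit beside it).
#' @return A `clock_model`.
#' @export
load_clock <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    term = readr::col_character(), weight = readr::col_character()))
  # strtod via as.numeric is correctly rounded, so 17-digit text round-trips
  df$weight <- as.numeric(df$weight)
  if (!identical(names(df), c("term", "weight")) ||
      nrow(df) < 1 || df$term[1] != "(Intercept)") {
    stop("malformed clock coefficient file: expected term,weight with an ",
         "(Intercept) first row", call. = FALSE)
  }
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing clock metadata sidecar: ", sp, call. = FALSE)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!identical(meta$format_version, 1L) && !identical(meta$format_version, 1)) {
    stop("unsupported clock file version: ", meta$format_version, call. = FALSE)
  }
  if (!meta$transform$kind %in% c("identity", "relative")) {
    stop("unknown transform kind in clock file: ", meta$transform$kind,
         call. = FALSE)
  }
  transform <- age_transform(meta$transform$kind,
                             unlist(meta$transform$max_lifespan))
  weights <- df$weight[-1]
  names(weights) <- df$term[-1]
  structure(
    list(weights = weights, intercept = df$weight[1], transform = transform,
         lambda = meta$lambda %||% NA_real_,
         training_meta = meta$training_meta,
         probe_universe = df$term[-1]),
    class = "clock_model")
}
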