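#' Construct a beta-value matrix
#'
#' A beta matrix holds DNA methylation fractions (beta values, in `[0, 1]`)
#' for a set of CpG sites measured across samples. Internally it is a plain
#' numeric matrix with sites as rows and samples as columns, carrying the
#' class `"beta_matrix"` so results print compactly and validate on
#' construction. Missing values (`NA`) are allowed and carried through;
#' nothing is imputed at this stage.
#'
#' @param values Numeric matrix, sites x samples. Row names are CpG ids,
#'   column names are sample ids; both are required and must be unique.
#' @return A validated `beta_matrix`.
#' @examples
#' m <- matrix(c(0.1, 0.5, 0.9, 0.2, 0.6, 0.8), nrow = 3,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' beta_matrix(m)
#' @export
beta_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (sites x samples).", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have row names (CpG ids) and column names (sample ids).",
         call. = FALSE)
  }
  validate_beta_matrix(structure(values, class = c("beta_matrix", "matrix", "array")))
}

validate_beta_matrix <- function(bm) {
  dup_sites <- unique(rownames(bm)[duplicated(rownames(bm))])
  if (length(dup_sites) > 0) {
    stop("Duplicate site ids: ", paste(utils::head(dup_sites, 5), collapse = ", "),
         call. = FALSE)
  }
  dup_samples <- unique(colnames(bm)[duplicated(colnames(bm))])
  if (length(dup_samples) > 0) {
    stop("Duplicate sample ids: ", paste(utils::head(dup_samples, 5), collapse = ", "),
         call. = FALSE)
  }
  v <- bm[!is.na(bm)]
  if (length(v) > 0 && (min(v) < 0 || max(v) > 1)) {
    bad <- which(!is.na(bm) & (bm < 0 | bm > 1), arr.ind = TRUE)[1, ]
    stop(sprintf("Beta values must lie in [0, 1]; offending value %.4g at site '%s', sample '%s'.",
                 bm[bad[1], bad[2]], rownames(bm)[bad[1]], colnames(bm)[bad[2]]),
         call. = FALSE)
  }
  bm
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d CpG sites x %d samples", nrow(x), ncol(x)))
  n_na <- sum(is.na(x))
  if (n_na > 0) cat(sprintf(" (%d missing values)", n_na))
  cat("\n")
  if (nrow(x) > 0 && ncol(x) > 0) {
    print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))), drop = FALSE])
    if (nrow(x) > 5 || ncol(x) > 5) cat("...\n")
  }
  invisible(x)
}

#' @export
`[.beta_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("beta_matrix", "matrix", "array") else out
  out
}

site_ids <- function(bm) rownames(bm)
sample_ids <- function(bm) colnames(bm)

#' Read a beta-value matrix from a delimited file
#'
#' Reads the GEO series-matrix style layout: one id column, one id header
#' row, tab-separated by default. The default dialect `"sites-as-rows"`
#' matches how 450K matrices are distributed; `"sites-as-columns"` reads the
#' transposed layout. Empty cells and `NA` become missing values; values
#' outside `[0, 1]` and duplicate ids are errors.
#'
#' @param path Path to a TSV/CSV file.
#' @param dialect Either `"sites-as-rows"` (default) or `"sites-as-columns"`.
#' @param delim Field delimiter, default tab.
#' @return A [beta_matrix()].
#' @seealso [write_beta_matrix()]
#' @export
read_beta_matrix <- function(path, dialect = c("sites-as-rows", "sites-as-columns"),
                             delim = "\t") {
  dialect <- match.arg(dialect)
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE,
                          na = c("", "NA"))
  if (ncol(df) < 2) stop("Expected an id column plus at least one value column.", call. = FALSE)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) > 0) {
        stop(sprintf("Non-numeric cell '%s' at row %d, column '%s' of %s.",
                     col[bad[1]], bad[1], names(vals)[j], path), call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (dialect == "sites-as-columns") m <- t(m)
  beta_matrix(m)
}

#' Write a beta-value matrix
#'
#' Inverse of [read_beta_matrix()]: sites as rows, sample ids in the header,
#' CpG ids in the first column, missing values written as empty cells.
#'
#' @param bm A [beta_matrix()].
#' @param path Output path.
#' @param delim Field delimiter, default tab.
#' @param digits Significant digits to print (default 6).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(bm, path, delim = "\t", digits = 6) {
  df <- tibble::as_tibble(round(unclass(bm), digits), rownames = "site_id")
  readr::write_delim(df, path, delim = delim, na = "")
  invisible(path)
}

#' Read a per-sample metadata sheet
#'
#' The sample sheet is a CSV with required columns `sample_id` and `age`
#' (chronological age in years, strictly positive), and optional columns
#' `sex` (`male`/`female`/`unknown`), `batch` (free-text study or chip
#' label) and any number of `cell_<type>` columns holding estimated
#' leukocyte fractions in `[0, 1]`.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per sample, classed `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  as_sample_sheet(df)
}

#' Validate a data frame as a sample sheet
#'
#' @param df Data frame with at least `sample_id` and `age` columns.
#' @return The validated tibble.
#' @export
as_sample_sheet <- function(df) {
  need <- setdiff(c("sample_id", "age"), names(df))
  if (length(need) > 0) {
    stop("Sample sheet is missing required column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  df$sample_id <- as.character(df$sample_id)
  df$age <- as.numeric(df$age)
  if (anyDuplicated(df$sample_id)) {
    stop("Duplicate sample_id in sample sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(df$age)) || any(df$age <= 0)) {
    stop("All ages must be positive real years.", call. = FALSE)
  }
  if ("sex" %in% names(df)) {
    bad <- setdiff(unique(df$sex), c("male", "female", "unknown", NA))
    if (length(bad) > 0) {
      stop("Unrecognised sex value(s): ", paste(bad, collapse = ", "),
           "; expected male/female/unknown.", call. = FALSE)
    }
  }
  cf <- cell_fraction_cols(df)
  for (cc in cf) {
    v <- df[[cc]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("Cell-fraction column '", cc, "' must lie in [0, 1].", call. = FALSE)
    }
  }
  class(df) <- c("sample_sheet", class(df))
  df
}

cell_fraction_cols <- function(sheet) grep("^cell_", names(sheet), value = TRUE)

#' Read a clock coefficient table
#'
#' The on-disk model is a two-column CSV (`site,coefficient`) with one
#' reserved row whose site label is `"Intercept"` — the layout in which
#' published clock coefficient tables circulate — plus an optional JSON
#' sidecar (`<path>.json`) carrying the age-transform parameters and
#' training metadata. Without a sidecar the default transform
#' (adult age 20, enabled) is assumed.
#'
#' @param path Path to the coefficient CSV.
#' @param sidecar Path to the JSON metadata sidecar; default `<path>.json`,
#'   used only if it exists.
#' @return A [clock_model()].
#' @seealso [write_clock_model()]
#' @export
read_clock_model <- function(path, sidecar = paste0(path, ".json")) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  if (!all(c("site", "coefficient") %in% names(df))) {
    stop("Coefficient table must have columns 'site' and 'coefficient'.", call. = FALSE)
  }
  is_int <- df$site == "Intercept"
  if (sum(is_int) == 0) stop("Coefficient table has no 'Intercept' row.", call. = FALSE)
  if (sum(is_int) > 1) stop("Coefficient table has multiple 'Intercept' rows.", call. = FALSE)
  sites <- df$site[!is_int]
  if (anyDuplicated(sites)) {
    stop("Duplicate CpG id(s) in coefficient table: ",
         paste(unique(sites[duplicated(sites)]), collapse = ", "), call. = FALSE)
  }
  coefs <- stats::setNames(as.numeric(df$coefficient[!is_int]), sites)
  spec <- transform_spec()
  meta <- list()
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$transform)) {
      spec <- transform_spec(adult_age = side$transform$adult_age,
                             enabled = side$transform$enabled)
    }
    if (!is.null(side$meta)) meta <- side$meta
  }
  clock_model(intercept = df$coefficient[is_int], coefficients = coefs,
              transform = spec, meta = meta)
}

#' Write a clock model to disk
#'
#' Writes the interoperable coefficient CSV plus a JSON sidecar with the
#' transform spec and training metadata.
#'
#' @param model A [clock_model()].
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_clock_model <- function(model, path) {
  df <- tibble::tibble(
    site = c("Intercept", names(model$coefficients)),
    coefficient = c(model$intercept, unname(model$coefficients))
  )
  readr::write_csv(df, path)
  jsonlite::write_json(
    list(transform = list(adult_age = model$transform$adult_age,
                          enabled = model$transform$enabled),
         meta = model$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a clock model
#'
#' A fitted epigenetic clock: an intercept and a sparse CpG-to-weight map on
#' the transformed-age scale, plus the transform specification needed to
#' report predictions in years. Zero-weight entries are dropped on
#' construction.
#'
#' @param intercept Intercept on the transformed-age scale.
#' @param coefficients Named numeric vector, CpG id -> weight.
#' @param transform A [transform_spec()].
#' @param meta Optional list of training provenance (alpha, lambda, rule,
#'   sample size, age span).
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(intercept, coefficients, transform = transform_spec(),
                        meta = list()) {
  stopifnot(is.numeric(intercept), length(intercept) == 1)
  if (length(coefficients) > 0) {
    if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
      stop("`coefficients` must be a named numeric vector of CpG ids.", call. = FALSE)
    }
    coefficients <- coefficients[coefficients != 0]
  }
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 transform = transform,
                 meta = meta),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> intercept %.4g, %d CpG sites", x$intercept,
              length(x$coefficients)))
  if (!is.null(x$meta$lambda_rule)) {
    cat(sprintf(" (alpha %.2g, lambda.%s = %.4g)", x$meta$alpha %||% NA,
                x$meta$lambda_rule, x$meta$lambda %||% NA))
  }
  cat(sprintf("\n  transform: adult_age %.3g, %s\n", x$transform$adult_age,
              if (isTRUE(x$transform$enabled)) "enabled" else "disabled"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a clock model into a coefficient tibble
#'
#' @param x A [clock_model()].
#' @param ... Unused.
#' @return A tibble with columns `term` (`"(Intercept)"` plus CpG ids) and
#'   `estimate`.
#' @export
tidy.clock_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' One-row summary of a clock model
#'
#' @param x A [clock_model()].
#' @param ... Unused.
#' @return A one-row tibble: number of sites, alpha, lambda, lambda rule,
#'   training n, and whether the age transform is enabled.
#' @export
glance.clock_model <- function(x, ...) {
  tibble::tibble(
    n_sites = length(x$coefficients),
    alpha = x$meta$alpha %||% NA_real_,
    lambda = x$meta$lambda %||% NA_real_,
    lambda_rule = x$meta$lambda_rule %||% NA_character_,
    n_train = x$meta$n_samples %||% NA_integer_,
    transform_enabled = isTRUE(x$transform$enabled),
    adult_age = x$transform$adult_age
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
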