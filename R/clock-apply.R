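#' Predict age from methylation with a fitted clock
#'
#' Computes the linear score `intercept + sum(coef_j * beta_j)` per sample
#' and inverts the model's age transform to report years. Model sites
#' absent from the matrix are handled per `missing_policy`: the default
#' `"error"` refuses (in a forensic setting silent imputation is dangerous);
#' `"impute_half"` substitutes beta 0.5 and reports the per-sample imputed
#' count. `NA` betas at model sites are treated the same way, per sample.
#'
#' @param model A [clock_model()] (or a `clock_fit`, whose model is used).
#' @param bm A [beta_matrix()] sharing at least one site with the model.
#' @param missing_policy `"error"` (default) or `"impute_half"`.
#' @param sheet Optional sample sheet; required only when the model carries
#'   `cell:` coefficient terms, which are looked up in the sheet's `cell_*`
#'   columns.
#' @return A tibble of class `prediction_result`: `sample_id`, `score`
#'   (transformed scale), `predicted_age` (years), `n_sites_used`,
#'   `n_sites_imputed`.
#' @export
predict_age <- function(model, bm, missing_policy = c("error", "impute_half"),
                        sheet = NULL) {
  if (inherits(model, "clock_fit")) model <- model$model
  stopifnot(inherits(model, "clock_model"))
  missing_policy <- match.arg(missing_policy)
  terms <- names(model$coefficients)
  cell_terms <- grep("^cell:", terms, value = TRUE)
  site_terms <- setdiff(terms, cell_terms)
  present <- intersect(site_terms, site_ids(bm))
  if (length(terms) > 0 && length(present) == 0 && length(cell_terms) == 0) {
    stop("None of the model's CpG sites are present in the beta matrix.",
         call. = FALSE)
  }
  absent <- setdiff(site_terms, present)
  X <- matrix(NA_real_, ncol(bm), length(terms),
              dimnames = list(sample_ids(bm), terms))
  if (length(present) > 0) X[, present] <- t(unclass(bm)[present, , drop = FALSE])
  if (length(cell_terms) > 0) {
    if (is.null(sheet)) {
      stop("Model uses cell-fraction terms; supply `sheet`.", call. = FALSE)
    }
    al <- align_sheet(bm, sheet)
    for (ct in cell_terms) {
      col <- paste0("cell_", sub("^cell:", "", ct))
      if (!col %in% names(al)) stop("Sheet lacks column '", col, "'.", call. = FALSE)
      X[, ct] <- al[[col]]
    }
  }
  n_missing <- rowSums(is.na(X))
  if (missing_policy == "error" && (length(absent) > 0 || any(n_missing > 0))) {
    bad <- union(absent, terms[colSums(is.na(X)) > 0])
    stop("Missing model site(s) in input: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (+%d more)", length(bad) - 10) else "",
         "; use missing_policy = \"impute_half\" to impute beta 0.5.",
         call. = FALSE)
  }
  X[is.na(X)] <- 0.5
  score <- model$intercept + drop(X %*% model$coefficients)
  out <- tibble::tibble(
    sample_id = sample_ids(bm),
    score = unname(score),
    predicted_age = inverse_transform_age(unname(score), model$transform),
    n_sites_used = length(terms) - unname(n_missing),
    n_sites_imputed = unname(n_missing)
  )
  class(out) <- c("prediction_result", class(out))
  out
}

#' Site overlap between two clocks
#'
#' Counts the CpG sites two clock site-lists share and expresses the
#' overlap as a percentage of the *first* clock's site count (the
#' convention of published clock-comparison tables), rounded
#' half-away-from-zero to one decimal.
#'
#' @param sites_a,sites_b Non-empty character vectors of CpG ids (or
#'   [clock_model()] objects, whose site names are used).
#' @param names Length-2 character vector naming the two clocks.
#' @return A one-row tibble: `clock_a`, `clock_b`, `n_a`, `n_b`,
#'   `n_overlap`, `percent`.
#' @examples
#' # 47 of 267 sites shared: 17.6%
#' clock_overlap(paste0("cg", 1:267), paste0("cg", c(1:47, 1000:1466)))
#' @export
clock_overlap <- function(sites_a, sites_b, names = c("clock_a", "clock_b")) {
  if (inherits(sites_a, "clock_model")) sites_a <- names(sites_a$coefficients)
  if (inherits(sites_b, "clock_model")) sites_b <- names(sites_b$coefficients)
  if (length(sites_a) == 0 || length(sites_b) == 0) {
    stop("Site lists must be non-empty.", call. = FALSE)
  }
  sites_a <- unique(sites_a); sites_b <- unique(sites_b)
  n_overlap <- length(intersect(sites_a, sites_b))
  tibble::tibble(
    clock_a = names[1], clock_b = names[2],
    n_a = length(sites_a), n_b = length(sites_b),
    n_overlap = n_overlap,
    percent = round_half_up(100 * n_overlap / length(sites_a), 1)
  )
}

# round half away from zero (printed-table convention; base round() is
# half-to-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read a plain-text CpG site list
#'
#' One CpG id per line, `#` comments allowed.
#'
#' @param path Path to the list file.
#' @return Character vector of unique site ids.
#' @export
read_site_list <- function(path) {
  read_blacklist(path)$site_ids
}

#' Summarise prediction errors
#'
#' The error-distribution report for a validation cohort: counts of
#' predictions within one year of truth and deviating by more than two and
#' three years, the worst absolute error, and the mean predicted age per
#' sex group. Errors are computed against `reference_age` when supplied
#' (e.g. 18.5 for a single-age cohort), otherwise against each sample's
#' sheet age.
#'
#' @param pred A `prediction_result` from [predict_age()].
#' @param sheet Sample sheet covering every predicted sample.
#' @param reference_age Optional single reference age in years.
#' @return A list of class `error_summary`: `counts` (one-row tibble with
#'   `n`, `n_within_1`, `n_over_2`, `n_over_3`, `max_abs_error`) and
#'   `by_sex` (mean predicted age per sex, when the sheet has `sex`).
#' @export
error_summary <- function(pred, sheet, reference_age = NULL) {
  sheet <- tibble::as_tibble(sheet)
  idx <- match(pred$sample_id, sheet$sample_id)
  if (anyNA(idx)) {
    stop("Prediction/sheet sample id mismatch: ",
         paste(utils::head(pred$sample_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  truth <- if (is.null(reference_age)) sheet$age[idx] else rep(reference_age, nrow(pred))
  err <- abs(pred$predicted_age - truth)
  counts <- tibble::tibble(
    n = length(err),
    n_within_1 = sum(err <= 1),
    n_over_2 = sum(err > 2),
    n_over_3 = sum(err > 3),
    max_abs_error = max(err)
  )
  by_sex <- NULL
  if ("sex" %in% names(sheet)) {
    by_sex <- tibble::tibble(sex = sheet$sex[idx],
                             predicted_age = pred$predicted_age) |>
      dplyr::group_by(.data$sex) |>
      dplyr::summarise(mean_predicted_age = mean(.data$predicted_age),
                       n = dplyr::n(), .groups = "drop")
  }
  structure(list(counts = counts, by_sex = by_sex), class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  c1 <- x$counts
  cat(sprintf("<error_summary> n = %d\n", c1$n))
  cat(sprintf("  within +/-1 y : %d (%.0f%%)\n", c1$n_within_1,
              100 * c1$n_within_1 / c1$n))
  cat(sprintf("  > 2 y         : %d (%.0f%%)\n", c1$n_over_2,
              100 * c1$n_over_2 / c1$n))
  cat(sprintf("  > 3 y         : %d\n", c1$n_over_3))
  cat(sprintf("  max |error|   : %.2f y\n", c1$max_abs_error))
  if (!is.null(x$by_sex)) print(x$by_sex)
  invisible(x)
}

#' @export
tidy.error_summary <- function(x, ...) x$counts
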