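#' Compute beta values from methylated/unmethylated intensities
#'
#' beta = M / (M + U + offset), elementwise. The stabilizing offset (default
#' 100 fluorescence units) keeps the ratio defined and strictly below 1 for
#' low-intensity probes.
#'
#' @param meth Numeric matrix of methylated signal intensities (sites x
#'   samples), nonnegative.
#' @param unmeth Numeric matrix of unmethylated intensities, same dimensions.
#' @param offset Nonnegative stabilizing constant, default 100.
#' @return A [beta_matrix()].
#' @examples
#' m <- matrix(c(0, 100, 900), dimnames = list(paste0("cg", 1:3), "s1"))
#' u <- matrix(0, 3, 1, dimnames = dimnames(m))
#' compute_beta(m, u)   # 0, 0.5, 0.9
#' @export
compute_beta <- function(meth, unmeth, offset = 100) {
  stopifnot(is.matrix(meth), is.matrix(unmeth), all(dim(meth) == dim(unmeth)),
            is.numeric(offset), length(offset) == 1, offset >= 0)
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE)) {
    stop("Signal intensities must be nonnegative.", call. = FALSE)
  }
  b <- meth / (meth + unmeth + offset)
  b[meth + unmeth + offset == 0] <- NA_real_
  dimnames(b) <- dimnames(meth)
  beta_matrix(b)
}

#' Read a probe blacklist
#'
#' Plain text, one CpG id per line; `#` starts a comment, blank lines are
#' skipped. Typical lists: SNP-associated probes, cross-reactive probes,
#' probes absent from the EPIC chip.
#'
#' @param path Path to the list file.
#' @param name Label for the list (default: file name without extension).
#' @return A list of class `probe_blacklist` with fields `name` and
#'   `site_ids`.
#' @export
read_blacklist <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  ids <- unique(lines[nzchar(lines)])
  probe_blacklist(ids, name = name)
}

#' @rdname read_blacklist
#' @param site_ids Character vector of CpG ids.
#' @export
probe_blacklist <- function(site_ids, name = "blacklist") {
  structure(list(name = name, site_ids = unique(as.character(site_ids))),
            class = "probe_blacklist")
}

#' Remove blacklisted probes from a beta matrix
#'
#' Drops every site appearing in any supplied blacklist. When a site occurs
#' in several lists the removal is attributed to the first list containing
#' it, in the order given, so the per-list counts in the log sum to the
#' total number of sites removed.
#'
#' @param bm A [beta_matrix()].
#' @param blacklists A single `probe_blacklist` or a list of them.
#' @return A list with `beta` (the filtered matrix, site order preserved)
#'   and `log` (a tibble with columns `blacklist`, `n_listed`, `n_removed`).
#' @export
filter_probes <- function(bm, blacklists) {
  if (inherits(blacklists, "probe_blacklist")) blacklists <- list(blacklists)
  stopifnot(all(vapply(blacklists, inherits, logical(1), "probe_blacklist")))
  attributed <- rep(NA_character_, nrow(bm))
  for (bl in blacklists) {
    hit <- is.na(attributed) & site_ids(bm) %in% bl$site_ids
    attributed[hit] <- bl$name
  }
  log <- tibble::tibble(
    blacklist = vapply(blacklists, `[[`, character(1), "name"),
    n_listed = vapply(blacklists, function(b) length(b$site_ids), integer(1)),
    n_removed = vapply(blacklists, function(b) sum(attributed == b$name, na.rm = TRUE),
                       integer(1))
  )
  list(beta = bm[is.na(attributed), , drop = FALSE], log = log)
}

#' Flag low-quality samples
#'
#' Two objective screens stand in for a full array QC pipeline: the fraction
#' of missing betas per sample, and the per-sample median beta (whole-blood
#' arrays centre well inside (0, 1); a median near 0 or 1 indicates a failed
#' hybridization). Samples are flagged, never removed — dropping them is a
#' deliberate downstream step, mirroring manual inspection of a QC summary.
#'
#' @param bm A [beta_matrix()].
#' @param max_missing Maximum tolerated missing fraction, default 0.05.
#' @param beta_median_range Acceptable median-beta interval, default
#'   `c(0.2, 0.8)`.
#' @return A tibble (class `sample_qc_report`) with one row per sample:
#'   `sample_id`, `missing_fraction`, `median_beta`, `flagged`, `reasons`
#'   (comma-separated, empty when unflagged).
#' @export
qc_samples <- function(bm, max_missing = 0.05, beta_median_range = c(0.2, 0.8)) {
  stopifnot(max_missing >= 0, max_missing <= 1, length(beta_median_range) == 2,
            beta_median_range[1] < beta_median_range[2])
  miss <- colMeans(is.na(bm))
  med <- apply(unclass(bm), 2, stats::median, na.rm = TRUE)
  reasons <- purrr::map2_chr(miss, med, function(m, md) {
    r <- character(0)
    if (m > max_missing) r <- c(r, "missing")
    if (is.na(md) || md < beta_median_range[1] || md > beta_median_range[2]) {
      r <- c(r, "median")
    }
    paste(r, collapse = ",")
  })
  out <- tibble::tibble(
    sample_id = sample_ids(bm),
    missing_fraction = unname(miss),
    median_beta = unname(med),
    flagged = nzchar(reasons),
    reasons = unname(reasons)
  )
  class(out) <- c("sample_qc_report", class(out))
  out
}
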