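#' Configuration for multimodal-site detection
#'
#' Some CpG sites show 2-3 discrete beta clusters (typically genotype-driven
#' — a SNP under the probe splits samples into homozygous/heterozygous
#' groups) instead of a continuous age trend. Such sites sabotage a linear
#' clock and are removed before training. Detection is by Gaussian kernel
#' density estimation on `[0, 1]` followed by peak counting: a local maximum
#' counts as a mode if its topographic prominence reaches a fraction of the
#' global density maximum, and modes closer together than a minimum beta
#' separation are merged (the higher peak wins).
#'
#' @param bandwidth KDE bandwidth on the beta scale; `NULL` (default) uses
#'   Silverman's rule-of-thumb per site, clipped below at `min_bandwidth`.
#' @param min_bandwidth Lower clip for the automatic bandwidth (default
#'   0.02) — avoids spiky densities at large n.
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   maximum density, default 0.1.
#' @param min_mode_separation Minimum beta distance between retained modes,
#'   default 0.2.
#' @param grid_size Number of density evaluation points on `[0, 1]`,
#'   default 512.
#' @param min_n Minimum non-missing samples per site for a modality call
#'   (default 10); sites below it are reported unimodal with a low-n note.
#' @return A list of class `modality_config`.
#' @export
modality_config <- function(bandwidth = NULL, min_bandwidth = 0.02,
                            min_prominence = 0.1, min_mode_separation = 0.2,
                            grid_size = 512, min_n = 10) {
  stopifnot(is.null(bandwidth) || (is.numeric(bandwidth) && bandwidth > 0),
            min_bandwidth > 0, min_prominence > 0,
            min_mode_separation > 0, min_mode_separation < 1,
            grid_size >= 16, min_n >= 2)
  structure(list(bandwidth = bandwidth, min_bandwidth = min_bandwidth,
                 min_prominence = min_prominence,
                 min_mode_separation = min_mode_separation,
                 grid_size = as.integer(grid_size), min_n = as.integer(min_n)),
            class = "modality_config")
}

# Topographic prominence of each local maximum of a density curve:
# height minus the higher of the two base saddles, where each base is the
# lowest density between the peak and the nearest strictly higher peak on
# that side (or the curve end if none).
peak_prominences <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- p; base_l <- h
    while (left > 1) {
      left <- left - 1
      base_l <- min(base_l, y[left])
      if (y[left] > h) break
    }
    right <- p; base_r <- h
    n <- length(y)
    while (right < n) {
      right <- right + 1
      base_r <- min(base_r, y[right])
      if (y[right] > h) break
    }
    h - max(base_l, base_r)
  }, numeric(1))
}

# Mode detection for one site's beta values; returns sorted mode locations.
detect_modes <- function(x, cfg) {
  x <- x[!is.na(x)]
  bw <- cfg$bandwidth
  if (is.null(bw)) bw <- max(stats::bw.nrd0(x), cfg$min_bandwidth)
  d <- stats::density(x, bw = bw, n = cfg$grid_size, from = 0, to = 1)
  y <- d$y
  n <- length(y)
  # interior local maxima (plateau-safe: strictly greater than one side,
  # not less than the other)
  is_peak <- c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n], FALSE) |
             c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(is_peak)
  if (length(peaks) == 0) peaks <- which.max(y)
  prom <- peak_prominences(y, peaks)
  # the global maximum always counts as a mode
  prom[which.max(y[peaks])] <- max(y)
  keep <- peaks[prom >= cfg$min_prominence * max(y)]
  # merge close modes, keeping the higher peak
  ord <- keep[order(y[keep], decreasing = TRUE)]
  accepted <- numeric(0)
  for (p in ord) {
    if (all(abs(d$x[p] - accepted) >= cfg$min_mode_separation)) {
      accepted <- c(accepted, d$x[p])
    }
  }
  sort(accepted)
}

#' Scan a beta matrix for multimodal CpG sites
#'
#' @param bm A [beta_matrix()].
#' @param cfg A [modality_config()].
#' @return A tibble (class `modality_report`) with one row per site:
#'   `site_id`, `n_modes`, `mode_locations` (list column of sorted betas),
#'   `multimodal`, `note` (`"low_n"` for sites with too few non-missing
#'   values to call, `""` otherwise).
#' @seealso [remove_multimodal()]
#' @export
modality_scan <- function(bm, cfg = modality_config()) {
  stopifnot(inherits(cfg, "modality_config"))
  if (nrow(bm) == 0 || ncol(bm) == 0) {
    stop("Cannot scan an empty beta matrix.", call. = FALSE)
  }
  rows <- purrr::map(seq_len(nrow(bm)), function(i) {
    x <- unclass(bm)[i, ]
    if (sum(!is.na(x)) < cfg$min_n) {
      return(list(n_modes = 1L, modes = stats::median(x, na.rm = TRUE), note = "low_n"))
    }
    modes <- detect_modes(x, cfg)
    list(n_modes = length(modes), modes = modes, note = "")
  })
  out <- tibble::tibble(
    site_id = site_ids(bm),
    n_modes = vapply(rows, function(r) as.integer(r$n_modes), integer(1)),
    mode_locations = purrr::map(rows, "modes"),
    note = vapply(rows, `[[`, character(1), "note")
  )
  out$multimodal <- out$n_modes >= 2L
  out <- out[, c("site_id", "n_modes", "mode_locations", "multimodal", "note")]
  class(out) <- c("modality_report", class(out))
  out
}

#' Drop sites flagged multimodal
#'
#' @param bm A [beta_matrix()].
#' @param report A `modality_report` from [modality_scan()] covering every
#'   site of `bm`.
#' @return The beta matrix restricted to unimodal sites, order preserved.
#' @export
remove_multimodal <- function(bm, report) {
  stopifnot(inherits(report, "modality_report"))
  missing <- setdiff(site_ids(bm), report$site_id)
  if (length(missing) > 0) {
    stop("Modality report does not cover site(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  flagged <- report$site_id[report$multimodal]
  bm[!site_ids(bm) %in% flagged, , drop = FALSE]
}
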