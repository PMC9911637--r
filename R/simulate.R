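#' Configuration for the synthetic methylation generator
#'
#' Generates beta matrices and sample sheets with the statistical structure
#' a methylation ageing pipeline assumes, so every stage is testable without
#' array downloads: age-linear CpGs (on the transformed-age scale, so the
#' age transform is exactly the right link), flat noise CpGs, SNP-like
#' multimodal CpGs with 2-3 well-separated clusters independent of age,
#' per-study batch shifts applied additively on the logit scale, and
#' optional blood cell fractions with (by default absent) cell-driven
#' signal.
#'
#' Defaults describe a desk-scale stand-in for a narrow-span training
#' cohort: 900 samples aged 12-25 over 2000 sites, 2% age-associated sites,
#' 5% multimodal sites, within-site noise sd 0.03 on the beta scale, and
#' three equal studies with logit shifts 0, +0.2, -0.2.
#'
#' @param n_samples Samples, default 900.
#' @param n_sites CpG sites, default 2000.
#' @param frac_signal Fraction of age-associated sites, default 0.02.
#' @param frac_multimodal Fraction of cluster-structured sites, default
#'   0.05.
#' @param age_range Age span in years, default `c(12, 25)`.
#' @param slope_range Absolute beta-scale slope per transformed-age unit
#'   for signal sites, default `c(0.2, 0.5)`; the sign is random.
#' @param noise_sd Within-site Gaussian noise sd on the beta scale,
#'   default 0.03.
#' @param batches Tibble/data frame with columns `label`, `n`, `shift`
#'   (additive logit offset), `scale` (variance multiplier); `n` must sum
#'   to `n_samples`. Default: three equal batches, shifts `0, 0.2, -0.2`,
#'   scale 1.
#' @param age_link `"transformed"` (default; site means follow the age
#'   transform), `"linear"` (means linear in raw age — a misspecified mode
#'   for robustness checks) or `"piecewise"` (an independent second slope
#'   above `break_age`, for narrow- vs broad-span experiments).
#' @param break_age Breakpoint for `age_link = "piecewise"`, default 25.
#' @param adult_age Knot of the transform used as the link, default 20.
#' @param cell_types Optional list with `names` (cell type labels),
#'   `concentration` (Dirichlet parameters) and optionally `effects`
#'   (types x sites logit-scale effect matrix). The default emulates
#'   estimated whole-blood fractions with *no* methylation effect.
#'   `NULL` disables cell fractions.
#' @param seed RNG seed, default 1.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 900, n_sites = 2000, frac_signal = 0.02,
                       frac_multimodal = 0.05, age_range = c(12, 25),
                       slope_range = c(0.2, 0.5), noise_sd = 0.03,
                       batches = NULL, age_link = c("transformed", "linear", "piecewise"),
                       break_age = 25, adult_age = 20,
                       cell_types = default_cell_types(), seed = 1) {
  age_link <- match.arg(age_link)
  if (is.null(batches)) {
    n_each <- c(rep(floor(n_samples / 3), 2), n_samples - 2 * floor(n_samples / 3))
    batches <- tibble::tibble(label = c("study1", "study2", "study3"),
                              n = n_each, shift = c(0, 0.2, -0.2), scale = 1)
  }
  batches <- tibble::as_tibble(batches)
  stopifnot(all(c("label", "n", "shift", "scale") %in% names(batches)),
            sum(batches$n) == n_samples,
            frac_signal + frac_multimodal <= 1, noise_sd > 0,
            length(age_range) == 2, age_range[1] < age_range[2],
            length(slope_range) == 2, slope_range[1] <= slope_range[2])
  structure(list(n_samples = as.integer(n_samples), n_sites = as.integer(n_sites),
                 frac_signal = frac_signal, frac_multimodal = frac_multimodal,
                 age_range = as.numeric(age_range),
                 slope_range = as.numeric(slope_range), noise_sd = noise_sd,
                 batches = batches, age_link = age_link, break_age = break_age,
                 adult_age = adult_age, cell_types = cell_types,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_cell_types <- function() {
  list(names = c("CD4T", "CD8T", "NK", "Bcell", "Mono", "Gran"),
       concentration = c(7.5, 4, 2.5, 2.5, 3.5, 30),
       effects = NULL)
}

#' Simulate a methylation training dataset
#'
#' Draws ages uniformly over the configured range, realizes per-site
#' generating parameters (baselines, slopes, cluster means and weights),
#' and emits values as site mean + Gaussian noise clipped to `[0, 1]`, with
#' batch shifts applied on the logit scale and back-transformed. The same
#' config (including seed) reproduces the output bit-identically.
#'
#' @param cfg A [sim_config()].
#' @return A list: `beta` (a [beta_matrix()]), `sheet` (a sample sheet
#'   tibble), `truth` (a `sim_truth` object recording per-site labels and
#'   generating parameters, reusable by [make_external_cohort()]). The
#'   fraction of clipped values is attached to `beta` as attribute
#'   `clip_fraction`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n_signal <- round(cfg$frac_signal * cfg$n_sites)
  n_multi <- round(cfg$frac_multimodal * cfg$n_sites)
  if (n_signal + n_multi > cfg$n_sites) stop("Site fractions exceed 1.", call. = FALSE)
  with_seed(cfg$seed, {
    ages <- stats::runif(cfg$n_samples, cfg$age_range[1], cfg$age_range[2])
    sex <- sample(c("male", "female"), cfg$n_samples, replace = TRUE)
    batch <- sample(rep(cfg$batches$label, cfg$batches$n))
    sites <- realize_sites(cfg, n_signal, n_multi)
    truth <- structure(list(sites = sites, batches = cfg$batches, cfg = cfg),
                       class = "sim_truth")
    sheet <- tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(cfg$n_samples)),
      age = ages, sex = sex, batch = batch
    )
    if (!is.null(cfg$cell_types)) {
      frac <- rdirichlet(cfg$n_samples, cfg$cell_types$concentration)
      colnames(frac) <- paste0("cell_", cfg$cell_types$names)
      sheet <- dplyr::bind_cols(sheet, tibble::as_tibble(frac))
    }
    bm <- generate_values(truth, sheet)
    list(beta = bm, sheet = as_sample_sheet(sheet), truth = truth)
  })
}

# Realize per-site generating parameters; RNG must already be seeded.
realize_sites <- function(cfg, n_signal, n_multi) {
  n <- cfg$n_sites
  label <- c(rep("signal", n_signal), rep("multimodal", n_multi),
             rep("noise", n - n_signal - n_multi))
  b0 <- stats::runif(n, 0.3, 0.7)   # baseline beta of signal sites
  slope <- slope2 <- rep(0, n)
  if (n_signal > 0) {
    draw_slope <- function(k) {
      sample(c(-1, 1), k, replace = TRUE) *
        stats::runif(k, cfg$slope_range[1], cfg$slope_range[2])
    }
    slope[seq_len(n_signal)] <- draw_slope(n_signal)
    slope2[seq_len(n_signal)] <- draw_slope(n_signal)  # used only when piecewise
  }
  base_mean <- stats::runif(n, 0.15, 0.85)
  modes <- probs <- vector("list", n)
  if (n_multi > 0) {
    for (i in n_signal + seq_len(n_multi)) {
      k <- sample(2:3, 1)
      if (k == 2) {
        m1 <- stats::runif(1, 0.1, 0.3)
        m <- c(m1, m1 + stats::runif(1, 0.4, 0.6))
        q <- stats::runif(1, 0.3, 0.7)
        p <- c(q, 1 - q)
      } else {
        m1 <- stats::runif(1, 0.05, 0.12)
        m <- cumsum(c(m1, stats::runif(2, 0.4, 0.43)))
        q <- stats::runif(1, 0.3, 0.7)
        p <- c(q^2, 2 * q * (1 - q), (1 - q)^2)
      }
      modes[[i]] <- m
      probs[[i]] <- p
    }
  }
  tibble::tibble(
    site_id = sprintf("cg%06d", seq_len(n)),
    label = label, b0 = b0, slope = slope, slope2 = slope2,
    base_mean = base_mean, modes = modes, probs = probs
  )
}

# Per-site mean matrix + noise + logit-scale batch shift. RNG must be
# seeded by the caller.
generate_values <- function(truth, sheet) {
  cfg <- truth$cfg
  sites <- truth$sites
  ages <- sheet$age
  n <- length(ages)
  spec <- transform_spec(adult_age = cfg$adult_age)
  f <- switch(cfg$age_link,
    transformed = transform_age(ages, spec),
    linear = (ages - mean(cfg$age_range)) / (diff(cfg$age_range) / 2) * 0.5,
    piecewise = transform_age(pmin(ages, cfg$break_age), spec)
  )
  f2 <- if (cfg$age_link == "piecewise") {
    pmax(transform_age(ages, spec) - transform_age(cfg$break_age, spec), 0)
  } else {
    rep(0, n)
  }
  mu <- matrix(0, nrow(sites), n, dimnames = list(sites$site_id, sheet$sample_id))
  for (i in seq_len(nrow(sites))) {
    # logistic age link; the configured slope is the beta-scale slope per
    # transformed-age unit at the baseline, so it is divided by the local
    # logistic derivative before entering the linear predictor
    d0 <- sites$b0[i] * (1 - sites$b0[i])
    mu[i, ] <- switch(sites$label[i],
      signal = stats::plogis(stats::qlogis(sites$b0[i]) +
                             (sites$slope[i] * f + sites$slope2[i] * f2) / d0),
      noise = rep(sites$base_mean[i], n),
      multimodal = {
        comp <- sample.int(length(sites$probs[[i]]), n, replace = TRUE,
                           prob = sites$probs[[i]])
        sites$modes[[i]][comp]
      })
  }
  if (!is.null(cfg$cell_types) && !is.null(cfg$cell_types$effects)) {
    frac <- as.matrix(sheet[, paste0("cell_", cfg$cell_types$names)])
    mu <- mu + t(cfg$cell_types$effects) %*% t(frac)
  }
  bshift <- cfg$batches$shift[match(sheet$batch, cfg$batches$label)]
  bscale <- cfg$batches$scale[match(sheet$batch, cfg$batches$label)]
  noise <- matrix(stats::rnorm(length(mu), 0, cfg$noise_sd), nrow(mu), n)
  noise <- sweep(noise, 2, sqrt(bscale), `*`)
  v <- mu + noise
  n_clip <- sum(v < 0 | v > 1)
  v <- pmin(pmax(v, 0), 1)
  shifted <- which(bshift != 0)
  if (length(shifted) > 0) {
    eps <- 1e-6
    vl <- stats::qlogis(pmin(pmax(v[, shifted, drop = FALSE], eps), 1 - eps))
    v[, shifted] <- stats::plogis(sweep(vl, 2, bshift[shifted], `+`))
  }
  bm <- beta_matrix(v)
  attr(bm, "clip_fraction") <- n_clip / length(v)
  bm
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

#' Simulate an external validation cohort from an existing truth
#'
#' Emulates an independent single-age test cohort: new samples all near one
#' target age, generated from the *same* realized site parameters as the
#' paired training draw, so a clock trained on that draw can be validated
#' on data it has never seen. By default the cohort carries the first
#' (unshifted) batch label; pass `batch` to place it in another study or a
#' new one with its own shift.
#'
#' @param truth The `sim_truth` from [simulate_dataset()].
#' @param target_age Cohort age in years, default 18.5.
#' @param n Cohort size, default 200.
#' @param jitter Half-width of the uniform age jitter in years, default
#'   0.5.
#' @param batch Either a label present in the truth's batch table, or a
#'   one-row data frame `label, shift, scale` defining a new study.
#'   Default: the truth's first batch.
#' @param seed RNG seed; defaults to a child of the training seed, so the
#'   pair (training draw, external cohort) is reproducible as a unit.
#' @return A list: `beta`, `sheet`.
#' @export
make_external_cohort <- function(truth, target_age = 18.5, n = 200, jitter = 0.5,
                                 batch = NULL, seed = NULL) {
  if (!inherits(truth, "sim_truth")) {
    stop("`truth` must come from simulate_dataset().", call. = FALSE)
  }
  cfg <- truth$cfg
  if (is.null(seed)) seed <- derive_seed(cfg$seed, 424242)
  if (is.null(batch)) {
    batch_row <- cfg$batches[1, ]
  } else if (is.character(batch)) {
    if (!batch %in% cfg$batches$label) {
      stop("Batch '", batch, "' not in the truth's batch table.", call. = FALSE)
    }
    batch_row <- cfg$batches[match(batch, cfg$batches$label), ]
  } else {
    batch_row <- tibble::as_tibble(batch)
  }
  with_seed(seed, {
    ages <- target_age + stats::runif(n, -jitter, jitter)
    sheet <- tibble::tibble(
      sample_id = sprintf("EX%04d", seq_len(n)),
      age = ages,
      sex = sample(c("male", "female"), n, replace = TRUE),
      batch = batch_row$label
    )
    if (!is.null(cfg$cell_types)) {
      frac <- rdirichlet(n, cfg$cell_types$concentration)
      colnames(frac) <- paste0("cell_", cfg$cell_types$names)
      sheet <- dplyr::bind_cols(sheet, tibble::as_tibble(frac))
    }
    cfg_ext <- cfg
    cfg_ext$batches <- batch_row
    truth_ext <- truth
    truth_ext$cfg <- cfg_ext
    bm <- generate_values(truth_ext, sheet)
    list(beta = bm, sheet = as_sample_sheet(sheet))
  })
}

#' Tidy the per-site simulation truth
#'
#' @param x A `sim_truth`.
#' @param ... Unused.
#' @return The per-site parameter tibble.
#' @export
tidy.sim_truth <- function(x, ...) x$sites

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d sites (%d signal, %d multimodal), %d batches\n",
              nrow(x$sites), sum(x$sites$label == "signal"),
              sum(x$sites$label == "multimodal"), nrow(x$batches)))
  invisible(x)
}
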