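#' Fit an empirical-Bayes location/scale batch model
#'
#' Study-of-origin (batch) effects shift and rescale methylation values and
#' can dominate biological signal. This fits the classic parametric
#' empirical-Bayes adjustment: per site, a mean model with batch indicators
#' plus protected covariates is fitted; the data are standardized on the
#' residual scale; per-batch location (`gamma`) and scale (`delta^2`)
#' estimates are shrunk toward common priors (normal on locations,
#' inverse-gamma on scales, hyperparameters by moment matching). Protected
#' covariates (typically chronological age — or, when age is unknown, the
#' age predicted by an existing clock, see
#' [protect_with_predicted_age()]) are part of the standardization mean, so
#' their signal survives the adjustment.
#'
#' In reference mode the standardization mean and pooled variance come from
#' the reference batch alone; the reference batch gets `gamma* = 0`,
#' `delta*^2 = 1` identically, so its samples pass through
#' [apply_batch_model()] bit-identical while every other batch is mapped
#' onto it. This is the mode that keeps separately-corrected training and
#' test data comparable.
#'
#' The adjustment operates directly on the beta scale (a logit option is
#' available via `logit = TRUE`, off by default).
#'
#' @param bm A [beta_matrix()] with no missing values.
#' @param sheet Sample sheet covering every sample of `bm`, with a `batch`
#'   column.
#' @param protected Character vector of sheet column names to protect
#'   (numeric covariates, e.g. `"age"`). Default none.
#' @param reference Optional batch label for reference mode.
#' @param parametric Only the parametric EB priors are implemented; `FALSE`
#'   errors.
#' @param logit Adjust on the logit scale instead of the beta scale.
#' @return An object of class `batch_model`.
#' @export
fit_batch_model <- function(bm, sheet, protected = character(), reference = NULL,
                            parametric = TRUE, logit = FALSE) {
  if (!parametric) {
    stop("Only the parametric empirical-Bayes priors are implemented.", call. = FALSE)
  }
  al <- align_sheet(bm, sheet)
  if (anyNA(bm)) {
    stop("Batch correction requires complete betas; impute or drop missing values first.",
         call. = FALSE)
  }
  batch <- factor(al$batch)
  if (nlevels(batch) < 2) stop("Need at least 2 batches.", call. = FALSE)
  nk <- table(batch)
  if (any(nk < 2)) {
    stop("Singleton batch(es): ", paste(names(nk)[nk < 2], collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(reference) && !reference %in% levels(batch)) {
    stop("Reference batch '", reference, "' not present in the sample sheet.",
         call. = FALSE)
  }
  miss <- setdiff(protected, names(al))
  if (length(miss) > 0) {
    stop("Protected covariate(s) not in sample sheet: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  mod <- protected_design(al, protected)

  Y <- unclass(bm)
  if (logit) Y <- stats::qlogis(pmin(pmax(Y, 1e-6), 1 - 1e-6))
  batchmod <- stats::model.matrix(~ 0 + batch)
  X <- cbind(batchmod, mod)
  if (qr(X)$rank < ncol(X)) {
    stop("Protected design is collinear with the batch indicators.", call. = FALSE)
  }
  K <- nlevels(batch)
  B <- solve(crossprod(X), crossprod(X, t(Y)))          # (K+P) x G
  nk <- as.numeric(table(batch))
  ref_idx <- if (is.null(reference)) NULL else match(reference, levels(batch))
  grand <- if (is.null(ref_idx)) {
    drop((nk / sum(nk)) %*% B[seq_len(K), , drop = FALSE])
  } else {
    B[ref_idx, ]
  }
  B_cov <- B[-seq_len(K), , drop = FALSE]               # P x G
  stand_mean <- outer(grand, rep(1, ncol(Y))) +
    if (ncol(mod) > 0) t(mod %*% B_cov) else 0
  resid <- Y - t(X %*% B)
  pool_idx <- if (is.null(ref_idx)) seq_len(ncol(Y)) else which(batch == reference)
  var_pooled <- pmax(rowMeans(resid[, pool_idx, drop = FALSE]^2), 1e-12)
  Z <- (Y - stand_mean) / sqrt(var_pooled)

  gamma_star <- delta_star <- matrix(0, K, nrow(Y),
                                     dimnames = list(levels(batch), rownames(Y)))
  for (k in seq_len(K)) {
    idx <- which(batch == levels(batch)[k])
    if (!is.null(ref_idx) && k == ref_idx) {
      gamma_star[k, ] <- 0
      delta_star[k, ] <- 1
      next
    }
    Zk <- Z[, idx, drop = FALSE]
    g_hat <- rowMeans(Zk)
    d_hat <- apply(Zk, 1, stats::var)
    eb <- eb_shrink(Zk, g_hat, d_hat)
    gamma_star[k, ] <- eb$gamma
    delta_star[k, ] <- eb$delta
  }
  structure(list(
    site_ids = rownames(Y),
    batches = levels(batch),
    reference = reference,
    protected = protected,
    grand_mean = grand,
    B_cov = B_cov,
    var_pooled = var_pooled,
    gamma_star = gamma_star,
    delta_star = delta_star,
    logit = logit
  ), class = "batch_model")
}

# Parametric EB shrinkage for one batch: normal prior on locations,
# inverse-gamma on scales, moment-matched hyperpriors, fixed-point solve.
eb_shrink <- function(Zk, g_hat, d_hat, conv = 1e-5, max_iter = 200) {
  n <- ncol(Zk)
  g_bar <- mean(g_hat)
  t2 <- stats::var(g_hat)
  m <- mean(d_hat); s2 <- stats::var(d_hat)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2
  g_old <- g_hat
  d_old <- d_hat
  for (i in seq_len(max_iter)) {
    g_new <- (n * t2 * g_hat + d_old * g_bar) / (n * t2 + d_old)
    sum2 <- rowSums((Zk - g_new)^2)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-8),
                  abs(d_new - d_old) / (abs(d_old) + 1e-8))
    g_old <- g_new; d_old <- d_new
    if (change < conv) break
  }
  list(gamma = g_old, delta = pmax(d_old, 1e-12))
}

#' @export
print.batch_model <- function(x, ...) {
  cat(sprintf("<batch_model> %d sites, %d batches%s\n", length(x$site_ids),
              length(x$batches),
              if (is.null(x$reference)) "" else paste0(" (reference: ", x$reference, ")")))
  if (length(x$protected) > 0) {
    cat("  protected:", paste(x$protected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy per-batch adjustment parameters
#'
#' @param x A `batch_model`.
#' @param ... Unused.
#' @return A tibble with one row per batch x site: `batch`, `site_id`,
#'   `gamma_star` (shift on the standardized scale), `delta_star_sq`
#'   (variance ratio).
#' @export
tidy.batch_model <- function(x, ...) {
  tidyr::expand_grid(batch = x$batches, site_id = x$site_ids) |>
    dplyr::mutate(gamma_star = as.vector(t(x$gamma_star)),
                  delta_star_sq = as.vector(t(x$delta_star)))
}

#' Apply a fitted batch model to a beta matrix
#'
#' Standardizes each sample with the model's mean structure (grand mean,
#' protected-covariate fit) and pooled variance, removes its batch's shrunk
#' location/scale effect, and restandardizes. Samples from the reference
#' batch are returned bit-identical. Values pushed outside `[0, 1]` are
#' clipped; the clip count is attached as attribute `n_clipped`.
#'
#' @param bm A [beta_matrix()] over (a subset of) the model's sites.
#' @param model A `batch_model` from [fit_batch_model()].
#' @param sheet Sample sheet with `batch` and the model's protected
#'   covariates for every sample of `bm`.
#' @return The corrected [beta_matrix()].
#' @export
apply_batch_model <- function(bm, model, sheet) {
  stopifnot(inherits(model, "batch_model"))
  al <- align_sheet(bm, sheet)
  unknown <- setdiff(unique(al$batch), model$batches)
  if (length(unknown) > 0) {
    stop("Batch label(s) not in the fitted model: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_sites <- setdiff(site_ids(bm), model$site_ids)
  if (length(missing_sites) > 0) {
    stop("Site(s) absent from the batch model: ",
         paste(utils::head(missing_sites, 5), collapse = ", "), call. = FALSE)
  }
  sidx <- match(site_ids(bm), model$site_ids)
  mod <- protected_design(al, model$protected)
  Y0 <- unclass(bm)
  Y <- if (model$logit) stats::qlogis(pmin(pmax(Y0, 1e-6), 1 - 1e-6)) else Y0
  stand_mean <- outer(model$grand_mean[sidx], rep(1, ncol(Y))) +
    if (ncol(mod) > 0) t(mod %*% model$B_cov[, sidx, drop = FALSE]) else 0
  vp <- model$var_pooled[sidx]
  Z <- (Y - stand_mean) / sqrt(vp)
  out <- Y
  for (b in unique(al$batch)) {
    idx <- which(al$batch == b)
    k <- match(b, model$batches)
    if (!is.null(model$reference) && b == model$reference) {
      out[, idx] <- Y0[, idx]   # reference passes through untouched
      next
    }
    Zadj <- (Z[, idx, drop = FALSE] - model$gamma_star[k, sidx]) /
      sqrt(model$delta_star[k, sidx])
    adj <- Zadj * sqrt(vp) + stand_mean[, idx, drop = FALSE]
    out[, idx] <- if (model$logit) stats::plogis(adj) else adj
  }
  n_clipped <- sum(out < 0 | out > 1)
  out <- pmin(pmax(out, 0), 1)
  res <- beta_matrix(out)
  attr(res, "n_clipped") <- n_clipped
  res
}

#' Fit and apply batch correction in one step
#'
#' @inheritParams fit_batch_model
#' @return The corrected [beta_matrix()]; the fitted model is attached as
#'   attribute `batch_model`.
#' @export
correct_batches <- function(bm, sheet, protected = character(), reference = NULL,
                            logit = FALSE) {
  model <- fit_batch_model(bm, sheet, protected = protected, reference = reference,
                           logit = logit)
  out <- apply_batch_model(bm, model, sheet)
  attr(out, "batch_model") <- model
  out
}

#' Batch-correct with a clock's predicted age as the protected variable
#'
#' In forensic use the chronological age of incoming samples is the unknown
#' being estimated, so it cannot serve as the protected covariate. This
#' variant predicts age with an existing clock (missing clock sites imputed
#' at beta 0.5), injects the prediction as the protected covariate, and runs
#' fit + apply in reference mode. A clock with no informative sites yields a
#' constant prediction, which is dropped with a warning (equivalent to no
#' protection).
#'
#' @param bm A [beta_matrix()].
#' @param sheet Sample sheet with a `batch` column.
#' @param clock A [clock_model()] sharing at least one site with `bm`.
#' @param reference Reference batch label.
#' @return The corrected [beta_matrix()] (attribute `batch_model` attached).
#' @export
protect_with_predicted_age <- function(bm, sheet, clock, reference) {
  pred <- predict_age(clock, bm, missing_policy = "impute_half")
  al <- align_sheet(bm, sheet)
  al$.predicted_age <- pred$predicted_age[match(al$sample_id, pred$sample_id)]
  protected <- ".predicted_age"
  if (stats::sd(al$.predicted_age) < 1e-10) {
    warning("Predicted age is constant; proceeding without a protected variable.",
            call. = FALSE)
    protected <- character(0)
  }
  correct_batches(bm, al, protected = protected, reference = reference)
}

#' PCA diagnostic for batch structure
#'
#' Projects samples onto their top principal components and scores each
#' component's association with batch by a one-way ANOVA F statistic
#' (between-batch over within-batch variance). Strong clustering of studies
#' on the leading components — a large F — is the signature of batch
#' effects; a successful correction drives the F statistics down.
#'
#' @param bm A [beta_matrix()] with no missing values.
#' @param sheet Sample sheet with a `batch` column.
#' @param n_components Number of components, default 5 (capped at
#'   `min(sites, samples) - 1`).
#' @return An object of class `batch_diagnostic`: list with `scores` (tibble
#'   of sample_id, batch, PC columns) and `association` (tibble of
#'   component, f_statistic, variance_explained).
#' @export
batch_pca <- function(bm, sheet, n_components = 5) {
  al <- align_sheet(bm, sheet)
  if (length(unique(al$batch)) < 2) stop("Need at least 2 batches.", call. = FALSE)
  if (anyNA(bm)) stop("PCA requires complete betas.", call. = FALSE)
  Y <- t(unclass(bm))
  if (max(apply(Y, 2, stats::var)) < 1e-12) {
    stop("All sites have zero variance; PCA is undefined.", call. = FALSE)
  }
  n_components <- min(n_components, min(dim(Y)) - 1)
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE, rank. = n_components)
  scores <- tibble::as_tibble(pc$x) |>
    dplyr::mutate(sample_id = al$sample_id, batch = al$batch, .before = 1)
  fstat <- vapply(seq_len(n_components), function(j) anova_f(pc$x[, j], al$batch),
                  numeric(1))
  ve <- pc$sdev[seq_len(n_components)]^2 / sum(pc$sdev^2)
  structure(list(
    scores = scores,
    association = tibble::tibble(component = paste0("PC", seq_len(n_components)),
                                 f_statistic = fstat, variance_explained = ve)
  ), class = "batch_diagnostic")
}

anova_f <- function(x, group) {
  group <- factor(group)
  n <- length(x); k <- nlevels(group)
  gm <- tapply(x, group, mean)
  ng <- tapply(x, group, length)
  ssb <- sum(ng * (gm - mean(x))^2)
  ssw <- sum((x - gm[group])^2)
  if (ssw < 1e-30) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' @export
print.batch_diagnostic <- function(x, ...) {
  cat(sprintf("<batch_diagnostic> %d samples, %d components\n",
              nrow(x$scores), nrow(x$association)))
  print(x$association)
  invisible(x)
}

#' @export
tidy.batch_diagnostic <- function(x, ...) x$association

# Align a sample sheet to a beta matrix's samples, requiring full coverage.
align_sheet <- function(bm, sheet) {
  sheet <- tibble::as_tibble(sheet)
  if (!"sample_id" %in% names(sheet)) {
    stop("Sample sheet needs a 'sample_id' column.", call. = FALSE)
  }
  miss <- setdiff(sample_ids(bm), sheet$sample_id)
  if (length(miss) > 0) {
    stop("Sample(s) missing from sheet: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  sheet[match(sample_ids(bm), sheet$sample_id), , drop = FALSE]
}

# Numeric design matrix for protected covariates (no intercept; the batch
# indicators span it).
protected_design <- function(sheet, protected) {
  if (length(protected) == 0) {
    return(matrix(0, nrow(sheet), 0))
  }
  m <- vapply(protected, function(p) as.numeric(sheet[[p]]), numeric(nrow(sheet)))
  m <- matrix(m, nrow = nrow(sheet), dimnames = list(NULL, protected))
  if (anyNA(m)) stop("Protected covariate(s) contain missing values.", call. = FALSE)
  m
}
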