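# Small two-batch dataset with a pure additive shift: batch B is batch A
# plus `shift` on every site, so the batch difference has no sampling noise
# and a mean-centering oracle predicts the corrected values exactly.
shifted_pair <- function(n_sites = 50, n_per = 100, shift = 0.1, seed = 5) {
  withr::with_seed(seed, {
    base <- matrix(runif(n_sites, 0.2, 0.6), n_sites, 1)
    A <- base[, rep(1, n_per)] + matrix(rnorm(n_sites * n_per, 0, 0.03),
                                        n_sites, n_per)
    A <- pmin(pmax(A, 0), 1)
    age <- runif(2 * n_per, 12, 25)
  })
  B <- pmin(pmax(A + shift, 0), 1)
  m <- cbind(A, B)
  dimnames(m) <- list(sprintf("cg%03d", seq_len(n_sites)),
                      sprintf("s%03d", seq_len(2 * n_per)))
  list(bm = beta_matrix(m),
       sheet = as_sample_sheet(tibble::tibble(
         sample_id = colnames(m), age = age,
         batch = rep(c("A", "B"), each = n_per))))
}

test_that("a planted additive shift is removed, matching a mean-centering oracle", {
  d <- shifted_pair()
  corr <- correct_batches(d$bm, d$sheet)
  mA <- rowMeans(unclass(corr)[, 1:100])
  mB <- rowMeans(unclass(corr)[, 101:200])
  expect_lt(max(abs(mA - mB)), 0.01)
  # oracle: per-site per-batch mean centering to the grand mean equalizes
  # batch means at exactly the grand mean; EB correction must land close
  oracle <- rowMeans(unclass(d$bm))
  expect_lt(max(abs(mA - oracle)), 0.02)
  expect_lt(max(abs(mB - oracle)), 0.02)
})

test_that("two identical batches shrink towards no adjustment", {
  withr::with_seed(6, {
    m <- matrix(rbeta(60 * 120, 5, 5), 60, 120,
                dimnames = list(sprintf("cg%03d", 1:60), sprintf("s%03d", 1:120)))
    sheet <- as_sample_sheet(tibble::tibble(
      sample_id = colnames(m), age = runif(120, 12, 25),
      batch = rep(c("A", "B"), 60)))
  })
  bm <- beta_matrix(m)
  model <- fit_batch_model(bm, sheet)
  expect_lt(max(abs(model$gamma_star)), 0.5)   # locations shrink toward 0
  corr <- apply_batch_model(bm, model, sheet)
  expect_lt(max(abs(unclass(corr) - unclass(bm))), 0.05)
})

test_that("reference-batch samples pass through bit-identical", {
  d <- shifted_pair(seed = 7)
  model <- fit_batch_model(d$bm, d$sheet, protected = "age", reference = "A")
  expect_equal(unname(model$gamma_star["A", ]), rep(0, 50))
  expect_equal(unname(model$delta_star["A", ]), rep(1, 50))
  corr <- apply_batch_model(d$bm, model, d$sheet)
  refs <- d$sheet$sample_id[d$sheet$batch == "A"]
  expect_identical(unclass(corr)[, refs], unclass(d$bm)[, refs])
  # a new dataset entirely in the reference batch is unchanged too
  sub <- d$bm[, refs[1:10]]
  out <- apply_batch_model(sub, model, d$sheet)
  expect_identical(strip_attrs(out), strip_attrs(sub))
})

test_that("apply is consistent with fit and rejects unknown batches", {
  d <- shifted_pair(seed = 8)
  model <- fit_batch_model(d$bm, d$sheet, protected = "age")
  c1 <- apply_batch_model(d$bm, model, d$sheet)
  c2 <- correct_batches(d$bm, d$sheet, protected = "age")
  expect_identical(strip_attrs(c1), strip_attrs(c2))
  bad <- d$sheet
  bad$batch[1] <- "C"
  expect_error(apply_batch_model(d$bm, model, bad), "not in the fitted model")
  # clipping is counted
  expect_true(attr(c1, "n_clipped") >= 0)
})

test_that("fit validates its design: singleton batches and collinearity", {
  d <- shifted_pair(seed = 9)
  one <- d$sheet
  one$batch[one$sample_id == "s001"] <- "C"
  expect_error(fit_batch_model(d$bm, one, protected = "age"), "Singleton")
  coll <- d$sheet
  coll$dup <- 1  # constant covariate is collinear with the batch indicators
  expect_error(fit_batch_model(d$bm, coll, protected = "dup"), "collinear")
  expect_error(fit_batch_model(d$bm, d$sheet, protected = "nope"),
               "not in sample sheet")
  expect_error(fit_batch_model(d$bm, d$sheet, parametric = FALSE), "parametric")
})

test_that("PCA diagnostic detects the planted batch and correction removes it", {
  sim <- default_sim()
  before <- batch_pca(sim$beta, sim$sheet)
  corr <- correct_batches(sim$beta, sim$sheet, protected = "age",
                          reference = "study1")
  after <- batch_pca(corr, sim$sheet)
  f_before <- max(before$association$f_statistic)
  f_after <- max(after$association$f_statistic)
  expect_gt(f_before, 50)
  expect_lt(f_after, f_before)  # strict decrease of the max per-PC F
  # the F statistic matches an independent group-means recomputation
  expect_equal(before$association$f_statistic[1],
               f_from_groups(before$scores$PC1, before$scores$batch))
  # permuted batch labels give F near the null
  perm <- sim$sheet
  perm$batch <- withr::with_seed(13, sample(perm$batch))
  fnull <- batch_pca(sim$beta, perm)$association$f_statistic
  expect_lt(mean(fnull), 3)
  expect_error(batch_pca(sim$beta, dplyr::mutate(sim$sheet, batch = "one")),
               "2 batches")
})

test_that("protected age signal survives correction (slopes within 10%)", {
  sim <- default_sim()
  corr <- correct_batches(sim$beta, sim$sheet, protected = "age",
                          reference = "study1")
  truth <- tidy(sim$truth)
  sig <- truth$site_id[truth$label == "signal"]
  f <- transform_age(sim$sheet$age, transform_spec(20))
  slope_of <- function(bm, s) unname(stats::coef(stats::lm(unclass(bm)[s, ] ~ f))[2])
  rel <- vapply(sig, function(s) {
    s0 <- slope_of(sim$beta, s)
    abs(slope_of(corr, s) - s0) / abs(s0)
  }, numeric(1))
  expect_lt(max(rel), 0.1)
})

test_that("predicted-age protection approximates true-age protection", {
  sim <- default_sim()
  fit <- train_clock(sim$beta, sim$sheet, training_config(seed = 2))
  with_pred <- protect_with_predicted_age(sim$beta, sim$sheet, fit$model,
                                          reference = "study1")
  with_true <- correct_batches(sim$beta, sim$sheet, protected = "age",
                               reference = "study1")
  # site-wise deviation small relative to the noise sd (0.03)
  expect_lt(max(abs(unclass(with_pred) - unclass(with_true))), 0.015)
  # degenerate clock: constant prediction falls back to unprotected fit
  null_clock <- clock_model(0.1, stats::setNames(numeric(0), character(0)))
  expect_warning(
    out <- protect_with_predicted_age(sim$beta[1:50, ], sim$sheet, null_clock,
                                      reference = "study1"),
    "constant")
  plain <- correct_batches(sim$beta[1:50, ], sim$sheet, reference = "study1")
  expect_equal(unclass(out), unclass(plain))
})
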