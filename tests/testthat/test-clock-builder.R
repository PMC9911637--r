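test_that("lambda selection follows the min and one-standard-error rules", {
  curve <- cv_curve(lambda = c(1, .5, .25, .125), mean_loss = c(4, 2, 1, 3),
                    se = rep(0.5, 4), nonzero = c(0, 2, 5, 5))
  expect_equal(select_lambda(curve, "min"), 0.25)
  # threshold = 1 + 0.5 = 1.5; only lambda = .25 qualifies
  expect_equal(select_lambda(curve, "1se"), 0.25)
  # flat losses: 1se picks the largest lambda (maximal sparsity under ties)
  flat <- cv_curve(lambda = c(1, .5, .25), mean_loss = c(1, 1, 1),
                   se = rep(0.1, 3), nonzero = 0:2)
  expect_equal(select_lambda(flat, "1se"), 1)
  expect_equal(select_lambda(flat, "min"), 1)  # which.min takes the first
})

test_that("1se rule matches an exhaustive scan on random curves", {
  withr::with_seed(17, {
    for (i in 1:25) {
      k <- sample(5:40, 1)
      curve <- cv_curve(lambda = sort(exp(runif(k, -6, 1)), decreasing = TRUE),
                        mean_loss = runif(k, 0.5, 5), se = runif(k, 0, 1),
                        nonzero = sort(sample(0:50, k, replace = TRUE)))
      i_min <- which.min(curve$mean_loss)
      thr <- curve$mean_loss[i_min] + curve$se[i_min]
      # oracle: scan every candidate
      best <- -Inf
      for (j in seq_len(k)) {
        if (curve$mean_loss[j] <= thr && curve$lambda[j] > best) {
          best <- curve$lambda[j]
        }
      }
      expect_equal(select_lambda(curve, "1se"), best)
      expect_equal(select_lambda(curve, "min"), curve$lambda[i_min])
    }
  })
})

test_that("mad_error is the median absolute prediction error in years", {
  expect_equal(mad_error(c(18, 19, 20), c(18, 19, 20)), 0)
  expect_equal(mad_error(c(18, 20, 25), c(18, 19, 20)), 1)
  expect_equal(mad_error(17.3, 18.0), 0.7)
  expect_error(mad_error(1:3, 1:2), "equal")
  # not the scale-estimator MAD: constant offset gives the offset itself
  expect_equal(mad_error(c(11, 12, 13), c(10, 11, 12)), 1)
})

test_that("penalized fits match a brute-force proximal-gradient solver", {
  fit_enet <- youthclock:::fit_enet
  enet_coef <- youthclock:::enet_coef
  withr::with_seed(7, {
    worst <- 0
    for (i in 1:20) {
      x <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("v", 1:5)))
      y <- drop(x %*% rnorm(5)) + rnorm(30, 0, 0.5)
      lam <- runif(1, 0.02, 0.3)
      g <- fit_enet(x, y, alpha = 0.5, lambda = c(1, 0.5, lam), thresh = 1e-14)
      o <- enet_fista(x, y, 0.5, lam)
      worst <- max(worst, max(abs(enet_coef(g, lam) - c(o$intercept, o$beta))))
    }
    expect_lt(worst, 1e-6)
  })
})

test_that("training recovers planted age-associated sites", {
  sim <- simulate_dataset(sim_config(n_samples = 600, n_sites = 1000,
                                     frac_signal = 0.02, frac_multimodal = 0,
                                     noise_sd = 0.03, seed = 11))
  fit <- train_clock(sim$beta, sim$sheet, training_config(seed = 11))
  truth <- tidy(sim$truth)
  planted <- truth$site_id[truth$label == "signal"]
  recovered <- intersect(names(fit$model$coefficients), planted)
  expect_gte(length(recovered), 15)
  # sparsity is non-increasing in lambda along the CV path
  expect_true(all(diff(fit$cv_curve$nonzero) * diff(fit$cv_curve$lambda) <= 0))
})

test_that("full shrinkage gives an intercept-only model; ridge keeps all", {
  fit_enet <- youthclock:::fit_enet
  enet_coef <- youthclock:::enet_coef
  withr::with_seed(19, {
    x <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("v", 1:8)))
    y <- drop(x %*% rnorm(8)) + rnorm(60, 0, 0.3)
  })
  g <- fit_enet(x, y, alpha = 0.5, lambda = c(1e4, 5e3, 2.5e3))
  cf <- enet_coef(g, 1e4)
  expect_equal(cf[-1], rep(0, 8))
  expect_equal(cf[1], mean(y))   # prediction collapses to the response mean

  sim <- simulate_dataset(sim_config(n_samples = 200, n_sites = 60,
                                     frac_multimodal = 0, seed = 23))
  ridge <- train_clock(sim$beta, sim$sheet,
                       training_config(alpha = 0, n_folds = 5, seed = 23))
  expect_equal(length(ridge$model$coefficients), 60)
})

test_that("training rejects missing betas and constant responses", {
  sim <- simulate_dataset(sim_config(n_samples = 150, n_sites = 40,
                                     frac_multimodal = 0, seed = 29))
  holey <- unclass(sim$beta)
  holey[1, 5] <- NA
  expect_error(train_clock(beta_matrix(holey), sim$sheet,
                           training_config(n_folds = 5)),
               "missing")
  const <- sim$sheet
  const$age <- 18
  expect_error(train_clock(sim$beta, const, training_config(n_folds = 5)),
               "constant")
})

test_that("repeated-split evaluation is deterministic and well-formed", {
  sim <- simulate_dataset(sim_config(n_samples = 300, n_sites = 200, seed = 37))
  ext <- make_external_cohort(sim$truth, n = 80)
  cfg <- training_config(n_folds = 5, n_repeats = 3, seed = 37)
  e1 <- evaluate_repeated(sim$beta, sim$sheet, ext$beta, ext$sheet, cfg)
  expect_equal(nrow(tidy(e1)), 3)
  expect_true(all(tidy(e1)$internal_mad >= 0))
  e2 <- evaluate_repeated(sim$beta, sim$sheet, ext$beta, ext$sheet,
                          training_config(n_folds = 5, n_repeats = 3, seed = 37))
  expect_identical(tidy(e1), tidy(e2))
  # summary covers the three measures
  expect_setequal(e1$summary$measure, c("internal_mad", "external_mad", "n_sites"))
  # training/external overlap is refused
  expect_error(evaluate_repeated(sim$beta, sim$sheet, sim$beta, sim$sheet, cfg),
               "overlap")
})

test_that("cell fractions append namespaced predictors; degenerate ones drop", {
  sim <- simulate_dataset(sim_config(n_samples = 120, n_sites = 30, seed = 41))
  x <- attach_cell_fractions(sim$beta, sim$sheet)
  expect_equal(ncol(x), 30 + 6)
  expect_equal(sum(grepl("^cell:", colnames(x))), 6)
  flat <- sim$sheet
  flat$cell_CD4T <- 0.25
  expect_warning(x2 <- attach_cell_fractions(sim$beta, flat), "zero-variance")
  expect_equal(ncol(x2), 30 + 5)
  nosheet <- sim$sheet[, c("sample_id", "age")]
  expect_error(attach_cell_fractions(sim$beta, nosheet), "cell_")
})
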