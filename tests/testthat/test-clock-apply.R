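test_that("prediction applies the linear score and inverse transform", {
  model <- clock_model(0, c(cg000001 = 1.0), transform_spec(adult_age = 20))
  bm <- beta_matrix(matrix(c(0, 0.5), 1, 2,
                           dimnames = list("cg000001", c("a", "b"))))
  pred <- predict_age(model, bm)
  expect_equal(pred$score, c(0, 0.5))
  expect_equal(pred$predicted_age[1], 20)           # inverse of 0
  expect_equal(pred$predicted_age[2], 20 + 0.5 * 21) # linear branch
  # all-zero coefficients: every sample gets inverse(intercept)
  null_model <- clock_model(0.25, c(cg000001 = 0))
  prednull <- predict_age(null_model, bm)
  expect_equal(prednull$predicted_age,
               rep(inverse_transform_age(0.25, transform_spec(20)), 2))
})

test_that("prediction is linear in beta values", {
  withr::with_seed(43, {
    coefs <- stats::setNames(rnorm(20, 0, 0.5), sprintf("cg%06d", 1:20))
    m <- matrix(runif(20 * 2), 20, 2,
                dimnames = list(names(coefs), c("a", "b")))
  })
  model <- clock_model(0.1, coefs)
  avg <- beta_matrix(matrix(rowMeans(m), 20, 1,
                            dimnames = list(names(coefs), "avg")))
  p <- predict_age(model, beta_matrix(m))
  pavg <- predict_age(model, avg)
  expect_equal(pavg$score, mean(p$score))
})

test_that("missing model sites follow the declared policy", {
  model <- clock_model(0, c(cg000001 = 1, cg000002 = 2))
  bm <- beta_matrix(matrix(0.4, 1, 1, dimnames = list("cg000001", "s1")))
  expect_error(predict_age(model, bm), "cg000002")
  pred <- predict_age(model, bm, missing_policy = "impute_half")
  expect_equal(pred$score, 0.4 * 1 + 0.5 * 2)
  expect_equal(pred$n_sites_imputed, 1)
  expect_equal(pred$n_sites_used, 1)
  # no shared sites at all is always an error
  off <- beta_matrix(matrix(0.4, 1, 1, dimnames = list("cg999999", "s1")))
  expect_error(predict_age(model, off, missing_policy = "impute_half"), "None")
})

test_that("clock overlap reproduces published comparison-table arithmetic", {
  paya_like <- sprintf("cg%06d", 1:267)
  # 47 shared of 514 -> 17.6% of the 267-site clock
  zhang_like <- sprintf("cg%06d", c(1:47, 10000 + 1:467))
  ov <- clock_overlap(paya_like, zhang_like, names = c("paya", "zhang"))
  expect_equal(ov$n_overlap, 47)
  expect_equal(ov$percent, 17.6)
  # 41 shared of 1892 -> 15.4%
  cabec_like <- sprintf("cg%06d", c(1:41, 20000 + 1:1851))
  expect_equal(clock_overlap(paya_like, cabec_like)$percent, 15.4)
  # 26 shared of 391 -> 9.7%
  skin_like <- sprintf("cg%06d", c(1:26, 30000 + 1:365))
  expect_equal(clock_overlap(paya_like, skin_like)$percent, 9.7)
  # identity and asymmetry of the denominator
  expect_equal(clock_overlap(paya_like, paya_like)$percent, 100)
  swapped <- clock_overlap(zhang_like, paya_like)
  expect_equal(swapped$n_overlap, 47)
  expect_equal(swapped$percent, round(100 * 47 / 514, 1))
  expect_error(clock_overlap(character(0), paya_like), "non-empty")
})

test_that("error summaries count nested thresholds against a reference age", {
  sheet <- as_sample_sheet(tibble::tibble(
    sample_id = sprintf("s%03d", 1:3), age = c(18.5, 18.5, 18.5),
    sex = c("male", "female", "male")))
  pred <- tibble::tibble(
    sample_id = sheet$sample_id,
    score = 0,
    predicted_age = 18.5 + c(0.5, 2.5, 3.5),
    n_sites_used = 1L, n_sites_imputed = 0L)
  class(pred) <- c("prediction_result", class(pred))
  es <- error_summary(pred, sheet, reference_age = 18.5)
  expect_equal(es$counts$n_within_1, 1)
  expect_equal(es$counts$n_over_2, 2)
  expect_equal(es$counts$n_over_3, 1)
  expect_equal(es$counts$max_abs_error, 3.5)
  expect_true(es$counts$n_over_3 <= es$counts$n_over_2)
  expect_equal(nrow(es$by_sex), 2)
  # exact predictions: zero everywhere
  exact <- pred
  exact$predicted_age <- rep(18.5, 3)
  es0 <- error_summary(exact, sheet, reference_age = 18.5)
  expect_equal(es0$counts$n_over_2, 0)
  expect_equal(es0$counts$max_abs_error, 0)
  # id mismatch errors
  bad <- pred
  bad$sample_id[1] <- "zzz"
  expect_error(error_summary(bad, sheet), "mismatch")
})

test_that("threshold counts are nested for random error patterns", {
  withr::with_seed(47, {
    for (i in 1:10) {
      n <- sample(20:200, 1)
      sheet <- as_sample_sheet(tibble::tibble(
        sample_id = sprintf("s%04d", 1:n), age = runif(n, 12, 25)))
      pred <- tibble::tibble(
        sample_id = sheet$sample_id, score = 0,
        predicted_age = sheet$age + rnorm(n, 0, 2),
        n_sites_used = 1L, n_sites_imputed = 0L)
      class(pred) <- c("prediction_result", class(pred))
      cc <- error_summary(pred, sheet)$counts
      expect_true(cc$n_over_3 <= cc$n_over_2)
      expect_true(cc$n_over_2 + cc$n_within_1 <= cc$n)
    }
  })
})
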