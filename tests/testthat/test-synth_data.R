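test_that("generation is deterministic and respects the cohort dimensions", {
  sp <- cohort_spec(n_subjects = 678, female_fraction = 290 / 678, seed = 1)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a, b)
  expect_equal(nrow(a), 678)

  ## gender counts within the binomial 95% band around 290 F / 388 M
  n_f <- sum(a$gender == 0)
  band <- qbinom(c(0.025, 0.975), 678, 290 / 678)
  expect_gte(n_f, band[1])
  expect_lte(n_f, band[2])

  ## strictly positive biomarkers and volumes, no missing values
  expect_false(anyNA(a))
  expect_true(all(as.matrix(a[ipfpfis:::BIOMARKERS]) > 0))
  expect_true(all(a$ipfp_volume > 0))
})

test_that("degenerate generator reduces to a two-point function of gender", {
  sp <- cohort_spec(n_subjects = 100, noise_sd = 0,
                    effect_coefs = c(intercept = 30000, gender = 9000,
                                     bmi = 0, age = 0, ratio = 0),
                    seed = 3)
  co <- generate_cohort(sp)
  expect_equal(unique(co$ipfp_volume[co$gender == 0]), 30000)
  expect_equal(unique(co$ipfp_volume[co$gender == 1]), 39000)
})

test_that("planted HMW-LMW correlation is realised on the log scale", {
  co <- generate_cohort(cohort_spec(n_subjects = 5000,
                                    adiponectin_hmw_lmw_corr = 0.58, seed = 7))
  r <- cor(log(co$adiponectin_HMW), log(co$adiponectin_LMW))
  expect_gte(r, 0.48)
  expect_lte(r, 0.68)
})

test_that("males receive a positive IPFP volume offset", {
  co <- small_cohort(n = 800, seed = 5)
  expect_gt(mean(co$ipfp_volume[co$gender == 1]),
            mean(co$ipfp_volume[co$gender == 0]))
})

test_that("OLS on the true generating variables recovers the planted coefficients", {
  sp <- cohort_spec(n_subjects = 2000, seed = 11)
  co <- generate_cohort(sp)
  ratio <- co$adipsin / co$CRP
  fit <- lm(ipfp_volume ~ gender + bmi + age + ratio, data = co)
  est <- coef(summary(fit))
  truth <- sp$effect_coefs[c("intercept", "gender", "bmi", "age", "ratio")]
  for (i in seq_along(truth))
    expect_lt(abs(est[i, "Estimate"] - truth[i]), 3 * est[i, "Std. Error"])
})

test_that("spec validation rejects malformed parameters", {
  expect_error(cohort_spec(n_subjects = 0), "positive")
  expect_error(cohort_spec(adiponectin_hmw_lmw_corr = 1.2), "corr")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
  expect_error(cohort_spec(female_fraction = 1.5), "female_fraction")
  expect_error(cohort_spec(ratio_feature = "adipsin/unobtainium"), "ratio_feature")
})

test_that("validation cohort has trial-like defaults and transfers noiselessly", {
  v1 <- generate_validation_cohort()
  v2 <- generate_validation_cohort()
  expect_identical(v1, v2)
  expect_equal(nrow(v1), 80)
  ## female-heavy split, as in a symptomatic-trial population
  expect_gt(mean(v1$gender == 0), 0.5)

  ## noiseless planted generator: a one-rule (linear) ANFIS trained on the
  ## training cohort predicts a noiseless validation cohort exactly
  tr <- noiseless_cohort(n = 300, seed = 21)
  va <- generate_validation_cohort(
    validation_cohort_spec(noise_sd = 0, seed = 22, bmi_shift = 0))
  feats <- c("gender", "bmi", "age", "adipsin/CRP")
  fm_tr <- build_features(tr)
  mod <- anfis_fcm(fm_tr, features = feats, n_rules = 1,
                   cfg = train_config(epochs = 1))
  res <- validate_external(mod, va, training_ids = tr$subject_id)
  expect_lt(res$metrics$MAPE, 1e-6)
})

test_that("cohort CSV round-trips through the documented header", {
  co <- small_cohort(n = 30, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  want <- as.data.frame(co)
  attr(want, "spec") <- NULL
  expect_equal(as.data.frame(back), want, tolerance = 1e-12)
})
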