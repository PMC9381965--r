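# Two-point sample with exact mean m and sample SD s (n-1 denominator).
two_point_sample <- function(m, s) c(m - s / sqrt(2), m + s / sqrt(2))

test_that("threshold formula reproduces printed control mean/threshold pairs", {
  # SDs back-solved from each printed (mean, threshold) pair via
  # (threshold - mean) / 2.576
  cases <- list(
    list(modality = "PD", mean = 1.21, threshold = 2.6),
    list(modality = "T2", mean = 1.37, threshold = 3.7),
    list(modality = "FLAIR", mean = 2.14, threshold = 6.2)
  )
  for (cs in cases) {
    s <- (cs$threshold - cs$mean) / 2.576
    calib <- calibrate_threshold(two_point_sample(cs$mean, s), cs$modality)
    expect_equal(calib$control_mean, cs$mean, tolerance = 1e-12)
    expect_equal(calib$control_sd, s, tolerance = 1e-12)
    expect_equal(calib$threshold, cs$threshold, tolerance = 1e-12)
  }
})

test_that("zero-variance controls degenerate to the mean with a warning", {
  expect_warning(calib <- calibrate_threshold(rep(1.0, 5), "PD"),
                 "zero control SD")
  expect_equal(calib$threshold, 1.0)
  expect_true(calib$degenerate)
})

test_that("calibration input contracts hold", {
  expect_error(calibrate_threshold(1.2, "PD"), class = "hod_too_few_controls")
  expect_error(calibrate_threshold(c(1.2, -0.1), "PD"),
               class = "hod_invalid_controls")
  expect_error(calibrate_threshold(c(1, 2), "FA"),
               class = "hod_invalid_modality")
})

test_that("calibration is permutation invariant and its mean term monotone", {
  x <- c(0.4, 1.1, 2.3, 0.9, 1.7)
  c1 <- calibrate_threshold(x, "T2")
  c2 <- calibrate_threshold(rev(x), "T2")
  expect_equal(c1$threshold, c2$threshold, tolerance = 1e-14)
  y <- x; y[3] <- y[3] + 1
  expect_gt(calibrate_threshold(y, "T2")$control_mean, c1$control_mean)
})

test_that("classification is strict at the boundary and laterality-aware", {
  calib <- calibrate_threshold(two_point_sample(1.21, (2.6 - 1.21) / 2.576),
                               "PD")
  meta <- subject_meta("p1", "patient", "right")

  above <- classify_subject(intensity_asymmetry(103, 100, "p1", "PD"),
                            calib, meta)  # 3.0% > 2.6%
  expect_true(above$exceeds_threshold)
  # left mean is higher but HOD was expected right: quantitative false positive
  expect_identical(above$higher_side, "left")
  expect_false(isTRUE(above$laterality_consistent))

  at <- classify_subject(intensity_asymmetry(102.6, 100, "p1", "PD"),
                         calib, meta)  # exactly 2.6%
  expect_false(at$exceeds_threshold)
  expect_true(is.na(at$laterality_consistent))

  # 4% with higher side matching the expected side
  ok <- classify_subject(intensity_asymmetry(100, 104, "p1", "PD"),
                         calib, meta)
  expect_true(ok$exceeds_threshold)
  expect_true(ok$laterality_consistent)

  t2_calib <- calibrate_threshold(c(1, 2), "T2")
  expect_error(classify_subject(intensity_asymmetry(103, 100, "p1", "PD"),
                                t2_calib, meta),
               class = "hod_modality_mismatch")
})

test_that("cohort exceedance rates reproduce the printed patient fractions", {
  make_calls <- function(n_exceed, n_total, modality) {
    do.call(rbind, lapply(seq_len(n_total), function(i) {
      data.frame(subject_id = paste0("p", i), modality = modality,
                 role = "patient", diff_percent = ifelse(i <= n_exceed, 5, 1),
                 exceeds_threshold = i <= n_exceed, higher_side = "left",
                 expected_side = "left",
                 laterality_consistent = ifelse(i <= n_exceed, TRUE, NA),
                 stringsAsFactors = FALSE)
    }))
  }
  expect_equal(cohort_exceedance_rate(make_calls(8, 15, "PD"), "PD"),
               100 * 8 / 15, tolerance = 1e-12)   # prints as 53.3%
  expect_equal(cohort_exceedance_rate(make_calls(4, 13, "FLAIR"), "FLAIR"),
               100 * 4 / 13, tolerance = 1e-12)   # prints as 30.8%
  expect_equal(cohort_exceedance_rate(make_calls(0, 10, "T2"), "T2"), 0)
  expect_error(cohort_exceedance_rate(make_calls(1, 2, "PD"), "T2"),
               class = "hod_empty_calls")
})

test_that("calibrated threshold contains ~99% of an independent control sample", {
  set.seed(314)
  train <- abs(rnorm(5000, 1.2, 0.5))
  calib <- calibrate_threshold(train, "PD")
  fresh <- abs(rnorm(5000, 1.2, 0.5))
  coverage <- mean(fresh < calib$threshold)
  expect_gte(coverage, 0.99)
})

test_that("noiseless planted effects above the diluted threshold are all detected", {
  spec <- cohort_spec(
    n_patients = 3, n_controls = 4, hod_prevalence_in_patients = 1,
    control_asymmetry_sd = c(PD = 0.3, T2 = 0.3, FLAIR = 0.3),
    patient_effect_distribution = list(distribution = "lognormal",
                                       meanlog = log(0.3), sdlog = 0.01,
                                       truncation = c(0.25, 0.5)),
    phantom = list(noise_sd = no_noise, hod_enlargement = 0),
    seed = 77
  )
  measured <- measure_cohort(spec)
  pd <- measured$structural[measured$structural$modality == "PD", ]
  calib <- calibrate_threshold(pd$diff_percent[pd$role == "control"], "PD")
  pats <- pd[pd$role == "patient", ]
  truth <- measured$truth
  for (i in seq_len(nrow(pats))) {
    meta <- subject_meta(pats$subject_id[i], "patient",
                         truth$expected_hod_side[truth$subject_id ==
                                                   pats$subject_id[i]])
    call <- classify_subject(
      intensity_asymmetry(pats$left_mean[i], pats$right_mean[i],
                          pats$subject_id[i], "PD"), calib, meta)
    expect_true(call$exceeds_threshold)
    expect_true(call$laterality_consistent)
  }
})
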