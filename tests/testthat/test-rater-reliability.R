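test_that("Fleiss kappa matches the hand-evaluated two-subject case", {
  # 2 subjects, 3 raters, 2 categories with count rows (2,1) and (1,2):
  # P_i = 1/3 each, p = (1/2, 1/2), Pe = 1/2, kappa = -1/3
  rows <- rbind(
    data.frame(rater_id = c("A", "B", "C"), subject_id = "s1", modality = "PD",
               hod_present = c(TRUE, TRUE, FALSE),
               side = c("left", "left", "none")),
    data.frame(rater_id = c("A", "B", "C"), subject_id = "s2", modality = "PD",
               hod_present = c(TRUE, FALSE, FALSE),
               side = c("left", "none", "none"))
  )
  k <- fleiss_kappa(validate_ratings(rows), "PD", mode = "presence")
  expect_equal(k$kappa, -1 / 3, tolerance = 1e-12)
})

test_that("unanimous mixed-category ratings give kappa 1; one category is undefined", {
  rows <- rbind(
    data.frame(rater_id = c("A", "B", "C"), subject_id = "s1", modality = "T2",
               hod_present = TRUE, side = "left"),
    data.frame(rater_id = c("A", "B", "C"), subject_id = "s2", modality = "T2",
               hod_present = FALSE, side = "none"),
    data.frame(rater_id = c("A", "B", "C"), subject_id = "s3", modality = "T2",
               hod_present = TRUE, side = "right")
  )
  k <- fleiss_kappa(validate_ratings(rows), "T2")
  expect_equal(k$kappa, 1)
  expect_false(k$undefined)

  all_neg <- rows
  all_neg$hod_present <- FALSE
  all_neg$side <- "none"
  k2 <- fleiss_kappa(validate_ratings(all_neg), "T2")
  expect_true(k2$undefined)
  expect_true(is.na(k2$kappa))
})

test_that("kappa agrees with an independent brute-force oracle on random small tables", {
  set.seed(2024)
  for (rep in 1:60) {
    N <- sample(2:6, 1)
    n <- sample(2:4, 1)
    k_cat <- sample(2:3, 1)
    cats <- c("none", "left", "right")[seq_len(k_cat)]
    mat <- matrix(sample(cats, N * n, replace = TRUE), N, n)
    rows <- do.call(rbind, lapply(seq_len(N), function(i) {
      data.frame(rater_id = paste0("R", seq_len(n)),
                 subject_id = paste0("s", i), modality = "PD",
                 hod_present = mat[i, ] != "none",
                 side = ifelse(mat[i, ] == "none", "none", mat[i, ]),
                 stringsAsFactors = FALSE)
    }))
    expected <- brute_force_kappa(mat)
    got <- fleiss_kappa(validate_ratings(rows), "PD")
    if (is.na(expected)) {
      expect_true(got$undefined)
    } else {
      expect_equal(got$kappa, expected, tolerance = 1e-10,
                   label = sprintf("N=%d n=%d k=%d rep=%d", N, n, k_cat, rep))
    }
  }
})

test_that("kappa is invariant to category relabeling and subject order", {
  set.seed(5)
  mat <- matrix(sample(c("none", "left", "right"), 15, replace = TRUE), 5, 3)
  build <- function(m) {
    do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
      data.frame(rater_id = paste0("R", 1:3), subject_id = paste0("s", i),
                 modality = "PD", hod_present = m[i, ] != "none",
                 side = ifelse(m[i, ] == "none", "none", m[i, ]),
                 stringsAsFactors = FALSE)
    }))
  }
  k1 <- fleiss_kappa(validate_ratings(build(mat)), "PD")
  swapped <- mat
  swapped[mat == "left"] <- "right"
  swapped[mat == "right"] <- "left"
  k2 <- fleiss_kappa(validate_ratings(build(swapped)), "PD")
  k3 <- fleiss_kappa(validate_ratings(build(mat[5:1, ])), "PD")
  expect_equal(k1$kappa, k2$kappa, tolerance = 1e-12)
  expect_equal(k1$kappa, k3$kappa, tolerance = 1e-12)
})

test_that("unbalanced rating tables are rejected", {
  rows <- data.frame(
    rater_id = c("A", "B", "A"), subject_id = c("s1", "s1", "s2"),
    modality = "PD", hod_present = FALSE, side = "none",
    stringsAsFactors = FALSE
  )
  expect_error(fleiss_kappa(validate_ratings(rows), "PD"),
               class = "hod_unbalanced")
})

test_that("per-rater diagnosis rates reproduce the printed worked example", {
  ids <- sprintf("p%02d", 1:15)
  meta <- patient_cohort_meta(ids)
  ratings <- make_ratings(c(8, 9, 10), ids)
  rates <- diagnosis_rates(ratings, meta, "PD")
  expect_equal(unname(rates$per_rater_diagnosis_pct),
               100 * c(8, 9, 10) / 15, tolerance = 1e-12)  # 53.3/60/66.7
  expect_equal(rates$mean_diagnosis_pct, 60, tolerance = 1e-12)
  expect_equal(rates$range_diagnosis_pct, 100 * c(8, 10) / 15,
               tolerance = 1e-12)
  # unanimous same-side positives on the first 8 subjects: consensus
  # counts only full agreement including side
  expect_equal(rates$consensus_pct, 100 * 8 / 15, tolerance = 1e-12)

  unanimous6 <- make_ratings(c(6, 6, 6), ids)
  expect_equal(diagnosis_rates(unanimous6, meta, "PD")$consensus_pct, 40)

  none <- make_ratings(c(0, 0, 0), ids)
  r0 <- diagnosis_rates(none, meta, "PD")
  expect_equal(r0$mean_diagnosis_pct, 0)
  expect_equal(r0$consensus_pct, 0)
})

test_that("consensus requires agreement on side, not just presence", {
  ids <- c("p1", "p2")
  meta <- patient_cohort_meta(ids)
  rows <- rbind(
    data.frame(rater_id = c("A", "B", "C"), subject_id = "p1", modality = "PD",
               hod_present = TRUE, side = c("left", "left", "right")),
    data.frame(rater_id = c("A", "B", "C"), subject_id = "p2", modality = "PD",
               hod_present = TRUE, side = "left")
  )
  rates <- diagnosis_rates(validate_ratings(rows), meta, "PD")
  expect_equal(rates$consensus_pct, 50)  # only p2 agrees on side
})

test_that("false-positive rates reproduce the printed control examples", {
  pids <- sprintf("p%02d", 1:15)
  cids <- sprintf("c%02d", 1:15)
  meta <- rbind(patient_cohort_meta(pids), control_cohort_meta(cids))

  # one positive control call in all ratings: per-rater 6.7/0/0, mean 2.2
  ratings <- rbind(make_ratings(c(0, 0, 0), pids),
                   make_ratings(c(1, 0, 0), cids))
  fp <- false_positive_rates(ratings, meta, "PD")
  expect_equal(unname(fp$control$per_rater_pct), c(100 / 15, 0, 0),
               tolerance = 1e-12)
  expect_equal(fp$control$mean_pct, 100 / 45, tolerance = 1e-12)  # 2.2%

  # counts 0, 1, 2 of 15 -> mean 6.7%
  ratings2 <- rbind(make_ratings(c(0, 0, 0), pids),
                    make_ratings(c(0, 1, 2), cids))
  fp2 <- false_positive_rates(ratings2, meta, "PD")
  expect_equal(fp2$control$mean_pct, 100 / 15, tolerance = 1e-12)
})

test_that("patient false positives count side-discordant calls only", {
  ids <- c("p1", "p2", "p3")
  meta <- patient_cohort_meta(ids, side = "left")
  aligned <- make_ratings(c(3, 3, 3), ids, side = "left")
  fp <- false_positive_rates(aligned, meta, "PD")
  expect_equal(fp$patient$mean_pct, 0)

  wrong <- make_ratings(c(3, 3, 3), ids, side = "right")
  fp2 <- false_positive_rates(wrong, meta, "PD")
  expect_equal(fp2$patient$mean_pct, 100)
})

test_that("subjects missing a modality drop out of that modality's rates", {
  ids <- sprintf("p%02d", 1:15)
  meta <- rbind(
    patient_cohort_meta(ids[1:13]),
    patient_cohort_meta(ids[14:15], modalities = c("PD", "T2"))  # no FLAIR
  )
  ratings <- rbind(make_ratings(c(5, 5, 5), ids, modality = "PD"),
                   make_ratings(c(5, 5, 5), ids[1:13], modality = "FLAIR"))
  r_pd <- diagnosis_rates(ratings, meta, "PD")
  r_fl <- diagnosis_rates(ratings, meta, "FLAIR")
  expect_equal(r_pd$n_subjects, 15L)
  expect_equal(r_fl$n_subjects, 13L)
  expect_equal(r_fl$per_rater_diagnosis_pct[[1]], 100 * 5 / 13,
               tolerance = 1e-12)  # 38.5%
  # missing ratings for a covered subject are an error
  bad <- make_ratings(c(5, 5, 5), ids[1:12], modality = "FLAIR")
  expect_error(diagnosis_rates(bad, meta, "FLAIR"), class = "hod_unbalanced")
})
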