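test_that("Lilliefors screen accepts normal and rejects two-point samples", {
  set.seed(101)
  x <- rnorm(500)
  res <- lilliefors_normality(x, mc_reps = 1000, seed = 1)
  expect_gt(res$p_value, 0.05)

  y <- rep(c(0, 1), 250) + rnorm(500, sd = 1e-6)
  res2 <- lilliefors_normality(y, mc_reps = 1000, seed = 1)
  expect_lt(res2$p_value, 0.05)

  expect_error(lilliefors_normality(rep(3, 10)), class = "hod_degenerate")
  expect_error(lilliefors_normality(c(1, 2, 3)), class = "hod_too_small")
})

test_that("Lilliefors KS distance matches the nortest implementation", {
  set.seed(17)
  for (n in c(10, 30, 120)) {
    x <- rgamma(n, shape = 2)
    ours <- lilliefors_normality(x, mc_reps = 50, seed = 1)$statistic
    ref <- unname(nortest::lillie.test(x)$statistic)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("paired t matches the closed form on a hand case", {
  a <- c(1, 2, 3); b <- c(2, 3, 5)
  res <- paired_t(a, b)
  d <- a - b
  t_exp <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$statistic, t_exp, tolerance = 1e-12)
  expect_equal(res$statistic, -4, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(-4, 2), tolerance = 1e-12)

  expect_error(paired_t(a, a + 1), class = "hod_degenerate")
  expect_error(paired_t(a, c(1, 2)), class = "hod_length_mismatch")

  set.seed(3)
  big <- rnorm(200)
  shifted <- paired_t(big, big + 1 + rnorm(200, sd = 0.1))
  expect_lt(shifted$p_value, 1e-10)
})

test_that("Welch t matches the textbook formula and handles degeneracy", {
  ident <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- welch_t(a, b)
  se2 <- var(a) / 3 + var(b) / 3
  t_exp <- (mean(a) - mean(b)) / sqrt(se2)
  df_exp <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$statistic, t_exp, tolerance = 1e-12)
  expect_equal(res$df, df_exp, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(t_exp, df_exp), tolerance = 1e-12)

  deg <- welch_t(c(2, 2, 2), c(5, 5))
  expect_true(is.infinite(deg$statistic))
  expect_equal(deg$p_value, 0)
  expect_match(deg$note, "degenerate")
})

test_that("Wilcoxon-Mann-Whitney: exact branch matches full enumeration", {
  res <- wilcoxon_mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)  # 2 / C(4,2)

  tied <- wilcoxon_mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tied$p_value, 1, tolerance = 1e-12)

  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    a <- rnorm(n1); b <- rnorm(n2, mean = runif(1, -1, 1))
    got <- wilcoxon_mann_whitney(a, b)
    expect_match(got$note, "exact")
    expect_equal(got$p_value, brute_force_wmw_p(a, b), tolerance = 1e-10,
                 label = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
  }
  expect_error(wilcoxon_mann_whitney(numeric(0), 1), class = "hod_too_small")
})

test_that("normal approximation tracks the exact WMW p at n=8 per group", {
  set.seed(23)
  for (rep in 1:10) {
    a <- rnorm(8); b <- rnorm(8, mean = runif(1, -0.5, 0.5))
    exact_p <- wilcoxon_mann_whitney(a, b)$p_value
    approx_p <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    )
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
})

test_that("Welch and WMW hold their nominal type-I level under the null", {
  set.seed(7001)
  reps <- 4000
  rej_w <- 0; rej_u <- 0
  for (i in seq_len(reps)) {
    a <- rnorm(12); b <- rnorm(12)
    if (welch_t(a, b)$p_value < 0.05) rej_w <- rej_w + 1
    if (wilcoxon_mann_whitney(a, b)$p_value < 0.05) rej_u <- rej_u + 1
  }
  expect_lt(abs(rej_w / reps - 0.05), 0.01)
  expect_lt(abs(rej_u / reps - 0.05), 0.01)
})

test_that("p-values live in [0,1] and two-sided tests are swap-symmetric", {
  set.seed(29)
  for (rep in 1:15) {
    a <- rnorm(sample(5:15, 1)); b <- rnorm(sample(5:15, 1), mean = 0.5)
    w1 <- welch_t(a, b); w2 <- welch_t(b, a)
    expect_equal(w1$p_value, w2$p_value, tolerance = 1e-12)
    expect_equal(w1$statistic, -w2$statistic, tolerance = 1e-12)
    u1 <- wilcoxon_mann_whitney(a, b); u2 <- wilcoxon_mann_whitney(b, a)
    expect_equal(u1$p_value, u2$p_value, tolerance = 1e-12)
    for (p in c(w1$p_value, u1$p_value)) {
      expect_gte(p, 0); expect_lte(p, 1)
    }
  }
})

test_that("group comparison routes by the normality screen", {
  set.seed(40)
  norm_route <- compare_groups(rnorm(40), rnorm(40, 0.2), mc_reps = 500)
  expect_identical(norm_route$test$test_name, "welch_t")
  skew_route <- compare_groups(rexp(40), rexp(40) + 0.2, mc_reps = 500)
  expect_identical(skew_route$test$test_name, "wilcoxon_mann_whitney")
  paired_route <- compare_groups(rnorm(30), rnorm(30, 0.1), paired = TRUE,
                                 mc_reps = 500)
  expect_identical(paired_route$test$test_name, "paired_t")
})

test_that("subgroup contrast orders FA/MD by PD status and guards empty groups", {
  dti <- rbind(
    data.frame(subject_id = paste0("p", 1:4), map = "FA",
               signed_diff_percent = c(-30, -40, -2, 1)),
    data.frame(subject_id = paste0("p", 1:4), map = "MD",
               signed_diff_percent = c(9, 12, -1, 0.5))
  )
  calls <- data.frame(
    subject_id = paste0("p", 1:4), modality = "PD", role = "patient",
    diff_percent = c(5, 6, 1, 1), exceeds_threshold = c(TRUE, TRUE, FALSE, FALSE),
    higher_side = "left", expected_side = "left", laterality_consistent = TRUE,
    stringsAsFactors = FALSE
  )
  contrast <- subgroup_contrast(dti, calls)
  expect_lt(contrast$FA$mean_diff_pd_plus, contrast$FA$mean_diff_pd_minus)
  expect_gt(contrast$MD$mean_diff_pd_plus, contrast$MD$mean_diff_pd_minus)
  expect_true(contrast$FA$computable)

  calls$exceeds_threshold <- FALSE
  no_plus <- subgroup_contrast(dti, calls)
  expect_false(no_plus$FA$computable)
  expect_null(no_plus$FA$test)

  expect_error(subgroup_contrast(
    rbind(dti, data.frame(subject_id = "p9", map = "FA",
                          signed_diff_percent = 0)), calls),
    class = "hod_unknown_subject")
})
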