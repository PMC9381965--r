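# Statistical comparisons: Lilliefors normality screening, paired and
# Welch t-tests, Wilcoxon-Mann-Whitney, and the PD+/PD- DTI subgroup
# contrast. Test selection follows the study's rule: normally distributed
# data go to t-tests, everything else to the rank test; all tests are
# two-sided and significance is declared at alpha = 0.05.

new_test_result <- function(test_name, statistic, p_value, n1, n2 = NA_integer_,
                            df = NA_real_, note = NA_character_,
                            alpha = 0.05) {
  structure(
    list(test_name = test_name, statistic = statistic, p_value = p_value,
         n1 = n1, n2 = n2, df = df, significant = is.finite(p_value) &&
           p_value < alpha, note = note),
    class = "hod_test_result"
  )
}

#' @export
print.hod_test_result <- function(x, ...) {
  cat(sprintf("<hod_test_result> %s: statistic %.4g, p = %.4g%s\n",
              x$test_name, x$statistic, x$p_value,
              if (!is.na(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

# Lilliefors' Kolmogorov-Smirnov distance of a sample against a normal
# with its own estimated mean/SD.
lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  fi <- pnorm(z)
  max((1:n) / n - fi, fi - (0:(n - 1)) / n)
}

#' Lilliefors (Kolmogorov-Smirnov) normality test
#'
#' Tests the composite null that the sample is normal with unknown mean
#' and SD. The null distribution of the KS distance with estimated
#' parameters is not the classical KS law, so the p-value is computed by
#' seeded Monte-Carlo: `mc_reps` standard-normal samples of size n, each
#' standardized by its own mean/SD, with
#' `p = (1 + #(D_null >= D)) / (mc_reps + 1)`.
#'
#' @param x numeric sample, `n >= 4`, nonzero variance.
#' @param mc_reps Monte-Carlo replicates (default 10000).
#' @param seed seed for the null simulation.
#' @return a `hod_test_result` with the KS distance as statistic.
#' @export
lilliefors_normality <- function(x, mc_reps = 10000L, seed = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop_hod("Lilliefors test needs n >= 4", "hod_too_small")
  if (sd(x) == 0) stop_hod("zero-variance sample", "hod_degenerate")
  d <- lilliefors_statistic(x)
  d_null <- with_seed(seed, {
    vapply(seq_len(mc_reps),
           function(i) lilliefors_statistic(rnorm(n)), numeric(1))
  })
  p <- (1 + sum(d_null >= d)) / (mc_reps + 1)
  new_test_result("lilliefors", d, p, n,
                  note = sprintf("Monte-Carlo p, %d replicates", mc_reps))
}

#' Paired t-test
#'
#' One-sample t on the elementwise differences, two-sided.
#'
#' @param sample_a,sample_b equal-length numeric vectors.
#' @return a `hod_test_result`.
#' @export
paired_t <- function(sample_a, sample_b) {
  if (length(sample_a) != length(sample_b)) {
    stop_hod("paired samples must have equal length", "hod_length_mismatch")
  }
  n <- length(sample_a)
  if (n < 2L) stop_hod("paired t needs n >= 2", "hod_too_small")
  if (sd(sample_a - sample_b) == 0) {
    stop_hod("zero variance of the paired differences", "hod_degenerate")
  }
  tt <- t.test(sample_a, sample_b, paired = TRUE)
  new_test_result("paired_t", unname(tt$statistic), tt$p.value, n,
                  df = unname(tt$parameter))
}

#' Welch two-sample t-test
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom, two-sided. Two zero-variance samples are a
#' degenerate input: equal constants give t = 0, p = 1; distinct
#' constants give an infinite statistic, reported as such with p = 0 and
#' a degeneracy note rather than an error.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return a `hod_test_result`.
#' @export
welch_t <- function(sample_a, sample_b) {
  n1 <- length(sample_a); n2 <- length(sample_b)
  if (n1 < 2L || n2 < 2L) stop_hod("Welch test needs n >= 2 per group",
                                   "hod_too_small")
  if (sd(sample_a) == 0 && sd(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(new_test_result("welch_t", 0, 1, n1, n2,
                             note = "degenerate: both samples constant"))
    }
    return(new_test_result(
      "welch_t", sign(mean(sample_a) - mean(sample_b)) * Inf, 0, n1, n2,
      note = "degenerate: both samples constant, means differ"
    ))
  }
  tt <- t.test(sample_a, sample_b, var.equal = FALSE)
  new_test_result("welch_t", unname(tt$statistic), tt$p.value, n1, n2,
                  df = unname(tt$parameter))
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Reports the Mann-Whitney U of the first sample. The p-value is exact
#' (full enumeration of the permutation distribution) when
#' `min(n1, n2) <= 8` and the pooled sample is tie-free; otherwise the
#' normal approximation with tie and continuity correction is used.
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @return a `hod_test_result`.
#' @export
wilcoxon_mann_whitney <- function(sample_a, sample_b) {
  n1 <- length(sample_a); n2 <- length(sample_b)
  if (n1 == 0L || n2 == 0L) stop_hod("samples must be nonempty", "hod_too_small")
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- min(n1, n2) <= 8L && !ties
  wt <- suppressWarnings(
    wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE)
  )
  new_test_result("wilcoxon_mann_whitney", unname(wt$statistic), wt$p.value,
                  n1, n2,
                  note = if (exact) "exact enumeration"
                         else "normal approximation, tie/continuity corrected")
}

#' Normality-routed group comparison
#'
#' Applies the study's decision rule: Lilliefors-screen the data (for
#' paired comparisons, the differences), then use the t-test (paired
#' within group, Welch between groups) when normality is not rejected and
#' the Wilcoxon-Mann-Whitney test (signed-rank for paired data)
#' otherwise. The routing decision is recorded in the result.
#'
#' @param sample_a,sample_b numeric vectors.
#' @param paired whether the samples are paired measurements.
#' @param mc_reps,seed Monte-Carlo settings for the normality screen.
#' @param alpha significance level of the screen and the final test.
#' @return list: `test` (a `hod_test_result`), `normality` (the screen
#'   results), `routing` (character description).
#' @export
compare_groups <- function(sample_a, sample_b, paired = FALSE,
                           mc_reps = 2000L, seed = 1L, alpha = 0.05) {
  if (paired) {
    screen <- list(differences = lilliefors_normality(sample_a - sample_b,
                                                      mc_reps, seed))
    normal <- screen$differences$p_value >= alpha
    test <- if (normal) {
      paired_t(sample_a, sample_b)
    } else {
      wt <- suppressWarnings(wilcox.test(sample_a, sample_b, paired = TRUE))
      new_test_result("wilcoxon_signed_rank", unname(wt$statistic),
                      wt$p.value, length(sample_a),
                      note = "nonparametric fallback for paired data")
    }
    routing <- if (normal) "normal differences -> paired t"
               else "non-normal differences -> Wilcoxon signed-rank"
  } else {
    screen <- list(a = lilliefors_normality(sample_a, mc_reps, seed),
                   b = lilliefors_normality(sample_b, mc_reps, seed + 1L))
    normal <- screen$a$p_value >= alpha && screen$b$p_value >= alpha
    test <- if (normal) welch_t(sample_a, sample_b)
            else wilcoxon_mann_whitney(sample_a, sample_b)
    routing <- if (normal) "both normal -> Welch t"
               else "non-normal -> Wilcoxon-Mann-Whitney"
  }
  list(test = test, normality = screen, routing = routing)
}

#' PD+/PD- DTI subgroup contrast
#'
#' Partitions patients by whether their PD asymmetry exceeded the
#' calibrated threshold (PD+ vs PD-) and compares the signed FA and MD
#' expected-side differences between the subgroups with the Welch test.
#' An empty subgroup yields a contrast with the test marked
#' not-computable instead of an error.
#'
#' @param dti data.frame of signed DTI asymmetries (columns `subject_id`,
#'   `map`, `signed_diff_percent`), as from [measure_cohort()].
#' @param pd_calls data.frame of PD [classify_subject()] rows; every DTI
#'   subject must have one.
#' @return named list (`FA`, `MD`) of class-`hod_contrast` lists:
#'   `mean_diff_pd_minus`, `mean_diff_pd_plus`, `n_minus`, `n_plus`,
#'   `computable`, `test`.
#' @export
subgroup_contrast <- function(dti, pd_calls) {
  pd_calls <- pd_calls[pd_calls$modality == "PD", , drop = FALSE]
  idx <- match(dti$subject_id, pd_calls$subject_id)
  if (anyNA(idx)) {
    stop_hod(sprintf("no PD call for DTI subject %s",
                     dti$subject_id[which(is.na(idx))[1]]),
             "hod_unknown_subject")
  }
  dti$pd_positive <- pd_calls$exceeds_threshold[idx]
  out <- lapply(c(FA = "FA", MD = "MD"), function(map) {
    rows <- dti[dti$map == map, , drop = FALSE]
    plus <- rows$signed_diff_percent[rows$pd_positive]
    minus <- rows$signed_diff_percent[!rows$pd_positive]
    res <- list(
      map = map,
      mean_diff_pd_minus = if (length(minus)) mean(minus) else NA_real_,
      mean_diff_pd_plus = if (length(plus)) mean(plus) else NA_real_,
      n_minus = length(minus), n_plus = length(plus)
    )
    if (length(plus) >= 2L && length(minus) >= 2L) {
      res$computable <- TRUE
      res$test <- welch_t(plus, minus)
    } else {
      res$computable <- FALSE
      res$test <- NULL
    }
    structure(res, class = "hod_contrast")
  })
  out
}
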