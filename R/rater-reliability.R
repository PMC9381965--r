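# Reviewer-based analysis: chance-corrected interrater agreement and the
# per-rater diagnosis / false-positive / consensus rates.

rating_category <- function(ratings, mode) {
  if (mode == "laterality") {
    ifelse(ratings$hod_present, ratings$side, "none")
  } else {
    ifelse(ratings$hod_present, "yes", "no")
  }
}

#' Fleiss' kappa for a fixed rater panel
#'
#' With N subjects, n raters and `n_ij` the number of raters assigning
#' subject i to category j:
#' `P_i = (sum_j n_ij^2 - n) / (n (n - 1))`, `Pbar = mean(P_i)`,
#' `p_j = sum_i n_ij / (N n)`, `Pe = sum_j p_j^2`, and
#' `kappa = (Pbar - Pe) / (1 - Pe)`.
#' When every rating falls in one category, `Pe = 1` and kappa is
#' undefined; this is returned as an explicit state (`undefined = TRUE`,
#' `kappa = NA`), not a number.
#'
#' @param ratings a ratings table (see [rating_record()]).
#' @param modality structural modality to evaluate.
#' @param mode `"laterality"` (categories none/HOD-left/HOD-right,
#'   the default, since raters reported presence and side) or
#'   `"presence"` (binary no/yes).
#' @param subjects optional metadata table; when given, only subjects
#'   with `role %in% roles` and the modality available enter the
#'   computation (the study computed agreement within the patient
#'   cohort).
#' @param roles roles kept when `subjects` is given.
#' @return object of class `hod_kappa`: `kappa`, `n_subjects`,
#'   `n_raters`, `categories`, `undefined`.
#' @export
fleiss_kappa <- function(ratings, modality, mode = c("laterality", "presence"),
                         subjects = NULL, roles = "patient") {
  mode <- match.arg(mode)
  assert_modality(modality, STRUCTURAL_MODALITIES)
  r <- ratings[ratings$modality == modality, , drop = FALSE]
  if (!is.null(subjects)) {
    keep <- subjects$subject_id[
      subjects$role %in% roles &
        vapply(seq_len(nrow(subjects)),
               function(i) has_modality(subjects[i, ], modality), logical(1))
    ]
    r <- r[r$subject_id %in% keep, , drop = FALSE]
  }
  if (nrow(r) == 0L) stop_hod("no ratings to evaluate", "hod_empty_ratings")
  if (anyDuplicated(r[, c("rater_id", "subject_id")])) {
    stop_hod("duplicate rating for a rater/subject pair", "hod_unbalanced")
  }
  per_subject <- table(r$subject_id)
  n_raters <- length(unique(r$rater_id))
  if (any(per_subject != n_raters)) {
    stop_hod("every subject must be rated once by every rater",
             "hod_unbalanced")
  }
  categories <- if (mode == "laterality") c("none", "left", "right")
                else c("no", "yes")
  cat_of <- factor(rating_category(r, mode), levels = categories)
  counts <- table(factor(r$subject_id), cat_of)  # N x k matrix n_ij
  N <- nrow(counts)
  n <- n_raters
  p_j <- colSums(counts) / (N * n)
  Pe <- sum(p_j^2)
  res <- list(modality = modality, n_subjects = N, n_raters = n,
              categories = categories, mode = mode)
  if (n < 2L || isTRUE(all.equal(Pe, 1))) {
    res$kappa <- NA_real_
    res$undefined <- TRUE
  } else {
    P_i <- (rowSums(counts^2) - n) / (n * (n - 1))
    res$kappa <- (mean(P_i) - Pe) / (1 - Pe)
    res$undefined <- FALSE
  }
  structure(res, class = "hod_kappa")
}

#' @export
print.hod_kappa <- function(x, ...) {
  cat(sprintf(
    "<hod_kappa> %s (%s): %s  [N=%d subjects, n=%d raters]\n",
    x$modality, x$mode,
    if (x$undefined) "undefined (single category)" else sprintf("%.4f", x$kappa),
    x$n_subjects, x$n_raters
  ))
  invisible(x)
}

# Subjects of a role with a modality available, plus the per-rater check
# that each rater rated all of them.
rated_subjects <- function(ratings, cohort, modality, role) {
  subj <- cohort[cohort$role == role, , drop = FALSE]
  subj <- subj[vapply(seq_len(nrow(subj)),
                      function(i) has_modality(subj[i, ], modality),
                      logical(1)), , drop = FALSE]
  r <- ratings[ratings$modality == modality &
                 ratings$subject_id %in% subj$subject_id, , drop = FALSE]
  for (rid in unique(ratings$rater_id)) {
    missing_subj <- setdiff(subj$subject_id, r$subject_id[r$rater_id == rid])
    if (length(missing_subj)) {
      stop_hod(sprintf("rater %s has no rating for subject %s (%s)",
                       rid, missing_subj[1], modality),
               "hod_unbalanced")
    }
  }
  list(subjects = subj, ratings = r)
}

#' Per-rater diagnosis rates and consensus
#'
#' Percentage of subjects each rater called HOD-positive, the mean and
#' range over raters, and the consensus rate: the fraction of subjects
#' that *all* raters called positive with the *same* side (a left-call
#' and a right-call describe different pathologies and do not agree).
#'
#' @param ratings ratings table.
#' @param cohort metadata table ([subject_meta()] rows).
#' @param modality structural modality.
#' @param role cohort to evaluate (default `"patient"`).
#' @return object of class `hod_rater_rates`: `per_rater_diagnosis_pct`
#'   (named), `mean_diagnosis_pct`, `range_diagnosis_pct`,
#'   `consensus_pct`, `n_subjects`.
#' @export
diagnosis_rates <- function(ratings, cohort, modality, role = "patient") {
  assert_modality(modality, STRUCTURAL_MODALITIES)
  rs <- rated_subjects(ratings, cohort, modality, role)
  n_subj <- nrow(rs$subjects)
  if (n_subj == 0L) stop_hod("no subjects to evaluate", "hod_empty_ratings")
  raters <- sort(unique(ratings$rater_id))
  per_rater <- vapply(raters, function(rid) {
    100 * mean(rs$ratings$hod_present[rs$ratings$rater_id == rid])
  }, numeric(1))
  consensus <- vapply(rs$subjects$subject_id, function(sid) {
    calls <- rs$ratings[rs$ratings$subject_id == sid, , drop = FALSE]
    all(calls$hod_present) && length(unique(calls$side)) == 1L
  }, logical(1))
  structure(
    list(
      modality = modality, role = role,
      per_rater_diagnosis_pct = per_rater,
      mean_diagnosis_pct = mean(per_rater),
      range_diagnosis_pct = range(per_rater),
      consensus_pct = 100 * mean(consensus),
      n_subjects = n_subj
    ),
    class = "hod_rater_rates"
  )
}

#' Per-rater false-positive rates
#'
#' Two notions of a false positive, mirroring how a study without a gold
#' standard can still count errors: in controls, any positive call is
#' false; in patients, a positive call whose side differs from the side
#' expected from the causative index lesion is false.
#'
#' @param ratings ratings table.
#' @param cohort metadata table with both roles.
#' @param modality structural modality.
#' @return list of class `hod_fp_rates` with elements `control` and
#'   `patient`, each holding `per_rater_pct`, `mean_pct`, `range_pct`,
#'   `n_subjects`.
#' @export
false_positive_rates <- function(ratings, cohort, modality) {
  assert_modality(modality, STRUCTURAL_MODALITIES)
  raters <- sort(unique(ratings$rater_id))
  out <- list(modality = modality)
  if (any(cohort$role == "control")) {
    rs <- rated_subjects(ratings, cohort, modality, "control")
    per <- vapply(raters, function(rid) {
      100 * mean(rs$ratings$hod_present[rs$ratings$rater_id == rid])
    }, numeric(1))
    out$control <- list(per_rater_pct = per, mean_pct = mean(per),
                        range_pct = range(per), n_subjects = nrow(rs$subjects))
  }
  if (any(cohort$role == "patient")) {
    rs <- rated_subjects(ratings, cohort, modality, "patient")
    expected <- rs$subjects$expected_hod_side[
      match(rs$ratings$subject_id, rs$subjects$subject_id)]
    fp <- rs$ratings$hod_present & rs$ratings$side != expected
    per <- vapply(raters, function(rid) {
      100 * mean(fp[rs$ratings$rater_id == rid])
    }, numeric(1))
    out$patient <- list(per_rater_pct = per, mean_pct = mean(per),
                        range_pct = range(per), n_subjects = nrow(rs$subjects))
  }
  structure(out, class = "hod_fp_rates")
}
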