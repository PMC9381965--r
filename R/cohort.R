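# Synthetic cohorts: patients with plantable unilateral HOD, disease
# controls with physiological residual asymmetry, and simulated raters.

#' Subject metadata
#'
#' @param subject_id identifier.
#' @param role `"patient"` or `"control"`.
#' @param expected_hod_side side where HOD is anticipated from the
#'   causative index lesion; must be `"none"` for controls and
#'   `"left"`/`"right"` for patients.
#' @param lesion_location free-text lesion description.
#' @param modalities_present character vector of available modality tags.
#' @return one-row data.frame (class `hod_subject_meta`);
#'   `modalities_present` is stored semicolon-separated.
#' @export
subject_meta <- function(subject_id, role, expected_hod_side,
                         lesion_location = "",
                         modalities_present = STRUCTURAL_MODALITIES) {
  if (!role %in% c("patient", "control")) {
    stop_hod("role must be 'patient' or 'control'", "hod_invalid_meta")
  }
  assert_side(expected_hod_side)
  if (role == "control" && expected_hod_side != "none") {
    stop_hod("controls must have expected_hod_side = 'none'", "hod_invalid_meta")
  }
  if (role == "patient" && expected_hod_side == "none") {
    stop_hod("patients must have expected_hod_side 'left' or 'right'",
             "hod_invalid_meta")
  }
  out <- data.frame(
    subject_id = as.character(subject_id), role = role,
    expected_hod_side = expected_hod_side,
    lesion_location = lesion_location,
    modalities_present = paste(modalities_present, collapse = ";"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("hod_subject_meta", "data.frame")
  out
}

has_modality <- function(meta_row, modality) {
  modality %in% strsplit(meta_row$modalities_present, ";", fixed = TRUE)[[1]]
}

#' Specify a synthetic cohort
#'
#' Defaults mirror a desk-scale HOD study: 15 patients with lesions of
#' the Guillain-Mollaret triangle and 15 disease controls. Controls (and
#' patients) receive a signed physiological residual asymmetry per
#' structural modality, drawn from a zero-mean normal whose SD is chosen
#' so the folded (unsigned) index has cohort means of order 1-2%:
#' `sd = target_mean * sqrt(pi/2)`, giving ~1.21% (PD), ~1.37% (T2) and
#' ~2.14% (FLAIR) at the defaults. Not every patient develops HOD: each
#' patient's olive effect is nonzero with probability
#' `hod_prevalence_in_patients`, in which case it is drawn from a
#' truncated log-normal (strictly positive, right-skewed).
#'
#' @param n_patients,n_controls cohort sizes.
#' @param control_asymmetry_sd named per-modality SD of the signed
#'   residual asymmetry, percent units.
#' @param patient_effect_distribution list describing the olive intensity
#'   effect distribution: `distribution` (only `"lognormal"`), `meanlog`,
#'   `sdlog`, `truncation` (interval the draw is clamped into).
#' @param hod_prevalence_in_patients fraction of patients who actually
#'   develop HOD.
#' @param phantom named list of [phantom_spec()] argument overrides
#'   applied to every subject's phantom.
#' @param seed master seed; the cohort is a pure function of the spec.
#' @return object of class `hod_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 15L, n_controls = 15L,
                        control_asymmetry_sd = c(PD = 1.21, T2 = 1.37,
                                                 FLAIR = 2.14) * sqrt(pi / 2),
                        patient_effect_distribution = list(
                          distribution = "lognormal",
                          meanlog = log(0.15), sdlog = 0.5,
                          truncation = c(0, 0.5)
                        ),
                        hod_prevalence_in_patients = 0.6,
                        phantom = list(hod_enlargement = 0.15),
                        seed = 1L) {
  if (n_patients < 0 || n_controls < 0) {
    stop_hod("cohort sizes must be nonnegative", "hod_invalid_spec")
  }
  if (hod_prevalence_in_patients < 0 || hod_prevalence_in_patients > 1) {
    stop_hod("hod_prevalence_in_patients must lie in [0, 1]", "hod_invalid_spec")
  }
  if (!identical(patient_effect_distribution$distribution, "lognormal")) {
    stop_hod("only the lognormal patient effect distribution is supported",
             "hod_invalid_spec")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
      control_asymmetry_sd = control_asymmetry_sd,
      patient_effect_distribution = patient_effect_distribution,
      hod_prevalence_in_patients = hod_prevalence_in_patients,
      phantom = phantom, seed = as.integer(seed)
    ),
    class = "hod_cohort_spec"
  )
}

#' Plan a cohort (the ground-truth table)
#'
#' Draws every subject's planted parameters: patients get an expected HOD
#' side (left/right with probability 1/2 each) and, with probability
#' `hod_prevalence_in_patients`, a positive olive intensity effect;
#' controls get no effect. All subjects get signed residual asymmetries
#' per structural modality. The plan is the ground truth that downstream
#' modules are evaluated against, and is a pure function of the spec.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame, one row per subject: `subject_id`, `role`,
#'   `expected_hod_side`, `hod_side` (planted side, `"none"` when no HOD
#'   developed), `hod_present`, `hod_intensity_effect`, `resid_PD`,
#'   `resid_T2`, `resid_FLAIR`, `phantom_seed`.
#' @export
cohort_plan <- function(spec) {
  stopifnot(inherits(spec, "hod_cohort_spec"))
  n <- spec$n_patients + spec$n_controls
  ids <- c(sprintf("P%03d", seq_len(spec$n_patients)),
           sprintf("C%03d", seq_len(spec$n_controls)))
  role <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
  ped <- spec$patient_effect_distribution
  with_seed(spec$seed, {
    expected <- ifelse(role == "patient",
                       sample(c("left", "right"), n, replace = TRUE), "none")
    develops <- role == "patient" &
      runif(n) < spec$hod_prevalence_in_patients
    effect <- ifelse(
      develops,
      pmin(pmax(rlnorm(n, ped$meanlog, ped$sdlog), ped$truncation[1]),
           ped$truncation[2]),
      0
    )
    resid <- sapply(STRUCTURAL_MODALITIES, function(m) {
      rnorm(n, 0, spec$control_asymmetry_sd[[m]])
    })
    seeds <- sample.int(.Machine$integer.max, n)
  })
  data.frame(
    subject_id = ids, role = role, expected_hod_side = expected,
    hod_side = ifelse(effect > 0, expected, "none"),
    hod_present = effect > 0, hod_intensity_effect = effect,
    resid_PD = resid[, "PD"], resid_T2 = resid[, "T2"],
    resid_FLAIR = resid[, "FLAIR"],
    phantom_seed = seeds, stringsAsFactors = FALSE
  )
}

# Phantom spec for one plan row, merging cohort-level overrides.
subject_phantom_spec <- function(spec, row) {
  args <- spec$phantom
  args$hod_side <- row$hod_side
  args$hod_intensity_effect <- row$hod_intensity_effect
  if (row$hod_side == "none") args$hod_enlargement <- 0
  args$residual_asymmetry <- c(PD = row$resid_PD, T2 = row$resid_T2,
                               FLAIR = row$resid_FLAIR)
  args$seed <- row$phantom_seed
  do.call(phantom_spec, args)
}

subject_meta_from_plan <- function(row) {
  mods <- if (row$role == "patient") {
    c(STRUCTURAL_MODALITIES, "FA", "MD")  # DTI acquired in patients only
  } else {
    STRUCTURAL_MODALITIES
  }
  subject_meta(row$subject_id, row$role, row$expected_hod_side,
               modalities_present = mods)
}

#' Generate a full synthetic cohort
#'
#' Materializes every subject's phantom volumes. For large cohorts prefer
#' [measure_cohort()], which generates, measures and discards subjects
#' one at a time.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `hod_cohort`: `subjects` (list of
#'   `list(phantom, meta)`), `truth` (the [cohort_plan()] table), `meta`
#'   (stacked metadata), `spec`.
#' @export
generate_cohort <- function(spec) {
  plan <- cohort_plan(spec)
  subjects <- lapply(seq_len(nrow(plan)), function(i) {
    row <- plan[i, ]
    list(
      phantom = generate_phantom(subject_phantom_spec(spec, row),
                                 row$subject_id),
      meta = subject_meta_from_plan(row)
    )
  })
  meta <- do.call(rbind, lapply(subjects, `[[`, "meta"))
  structure(list(subjects = subjects, truth = plan, meta = meta, spec = spec),
            class = "hod_cohort")
}

#' Measure a cohort's asymmetries (streaming)
#'
#' Generates each subject's phantom, runs the quadrant segmentation and
#' asymmetry metrics on every available modality, and discards the
#' volumes, so memory stays flat in the cohort size. DTI asymmetries are
#' computed for patients only (controls have no DTI and no expected
#' side).
#'
#' @param spec a [cohort_spec()].
#' @return list: `structural` (data.frame subject_id, role, modality,
#'   left_mean, right_mean, higher_side, diff_percent), `dti` (data.frame
#'   subject_id, map, mean_expected_side, mean_contralateral,
#'   signed_diff_percent), `truth`, `meta`.
#' @export
measure_cohort <- function(spec) {
  plan <- cohort_plan(spec)
  structural <- list()
  dti <- list()
  metas <- list()
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    meta <- subject_meta_from_plan(row)
    metas[[i]] <- meta
    ph <- generate_phantom(subject_phantom_spec(spec, row), row$subject_id)
    for (m in STRUCTURAL_MODALITIES) {
      if (!has_modality(meta, m)) next
      mm <- measure_phantom(ph, m)
      a <- intensity_asymmetry(mm$left_mean, mm$right_mean, row$subject_id, m)
      structural[[length(structural) + 1L]] <- data.frame(
        subject_id = row$subject_id, role = row$role, modality = m,
        left_mean = mm$left_mean, right_mean = mm$right_mean,
        higher_side = a$higher_side, diff_percent = a$diff_percent,
        stringsAsFactors = FALSE
      )
    }
    if (row$role == "patient") {
      for (map in c("FA", "MD")) {
        if (!has_modality(meta, map)) next
        mm <- measure_phantom(ph, map)
        exp_mean <- if (row$expected_hod_side == "left") mm$left_mean else mm$right_mean
        ctr_mean <- if (row$expected_hod_side == "left") mm$right_mean else mm$left_mean
        d <- dti_asymmetry(exp_mean, ctr_mean, row$subject_id, map)
        dti[[length(dti) + 1L]] <- data.frame(
          subject_id = row$subject_id, map = map,
          mean_expected_side = exp_mean, mean_contralateral = ctr_mean,
          signed_diff_percent = d$signed_diff_percent,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  list(
    structural = do.call(rbind, structural),
    dti = if (length(dti)) do.call(rbind, dti) else NULL,
    truth = plan,
    meta = do.call(rbind, metas)
  )
}

#' Specify a simulated rater
#'
#' @param rater_id identifier.
#' @param sensitivity probability of calling a true HOD positive.
#' @param specificity probability of calling a HOD-free subject negative.
#' @param laterality_error_rate probability that a correct positive call
#'   names the wrong side.
#' @param seed rater-level seed.
#' @return object of class `hod_rater_model`.
#' @export
rater_model <- function(rater_id, sensitivity, specificity,
                        laterality_error_rate = 0, seed = 1L) {
  for (p in c(sensitivity, specificity, laterality_error_rate)) {
    if (!is_scalar_number(p) || p < 0 || p > 1) {
      stop_hod("rater probabilities must lie in [0, 1]", "hod_invalid_spec")
    }
  }
  structure(
    list(rater_id = as.character(rater_id), sensitivity = sensitivity,
         specificity = specificity,
         laterality_error_rate = laterality_error_rate,
         seed = as.integer(seed)),
    class = "hod_rater_model"
  )
}

#' Three default reviewers
#'
#' Experienced but imperfect readers: high sensitivity, specificities
#' chosen so control false-positive rates land in the single-digit
#' percent range, and a small laterality error rate.
#'
#' @param seed base seed; rater seeds are derived from it.
#' @return list of three [rater_model()]s.
#' @export
default_raters <- function(seed = 1L) {
  seeds <- derive_seeds(seed, 3L)
  list(
    rater_model("R1", sensitivity = 0.90, specificity = 0.92,
                laterality_error_rate = 0.05, seed = seeds[1]),
    rater_model("R2", sensitivity = 0.80, specificity = 0.95,
                laterality_error_rate = 0.05, seed = seeds[2]),
    rater_model("R3", sensitivity = 0.85, specificity = 0.97,
                laterality_error_rate = 0.05, seed = seeds[3])
  )
}

#' Simulate blinded rater decisions
#'
#' Each rater reviews every subject's available structural datasets
#' independently per modality. For a subject with true HOD the rater
#' calls it positive with probability `sensitivity` and, when positive,
#' reports the wrong side with probability `laterality_error_rate`; for a
#' HOD-free subject the rater calls a false positive with probability
#' `1 - specificity`, with a uniformly random side.
#'
#' @param truth a [cohort_plan()] table (or the `truth` element of a
#'   cohort).
#' @param raters list of [rater_model()]s.
#' @param meta optional metadata table restricting modalities per subject;
#'   defaults to all structural modalities for everyone.
#' @return validated ratings data.frame (see [rating_record()]).
#' @export
simulate_raters <- function(truth, raters, meta = NULL) {
  if (!all(c("subject_id", "hod_present", "hod_side") %in% names(truth))) {
    stop_hod("truth table must carry subject_id, hod_present, hod_side",
             "hod_invalid_spec")
  }
  if (!is.null(meta)) {
    missing_subj <- setdiff(truth$subject_id, meta$subject_id)
    if (length(missing_subj)) {
      stop_hod(sprintf("no metadata for subject %s", missing_subj[1]),
               "hod_unknown_subject")
    }
  }
  flip <- c(left = "right", right = "left")
  out <- list()
  for (r in raters) {
    stopifnot(inherits(r, "hod_rater_model"))
    rows <- with_seed(r$seed, {
      recs <- list()
      for (i in seq_len(nrow(truth))) {
        subj <- truth[i, ]
        mods <- STRUCTURAL_MODALITIES
        if (!is.null(meta)) {
          mrow <- meta[meta$subject_id == subj$subject_id, , drop = FALSE][1, ]
          mods <- intersect(mods,
                            strsplit(mrow$modalities_present, ";")[[1]])
        }
        for (m in mods) {
          if (isTRUE(subj$hod_present)) {
            positive <- runif(1) < r$sensitivity
            side <- if (!positive) {
              "none"
            } else if (runif(1) < r$laterality_error_rate) {
              flip[[subj$hod_side]]
            } else {
              subj$hod_side
            }
          } else {
            positive <- runif(1) < (1 - r$specificity)
            side <- if (positive) sample(c("left", "right"), 1) else "none"
          }
          recs[[length(recs) + 1L]] <- data.frame(
            rater_id = r$rater_id, subject_id = subj$subject_id,
            modality = m, hod_present = positive, side = side,
            stringsAsFactors = FALSE
          )
        }
      }
      do.call(rbind, recs)
    })
    out[[length(out) + 1L]] <- rows
  }
  validate_ratings(do.call(rbind, out))
}
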