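# End-to-end analysis over a synthetic cohort: measure asymmetries,
# calibrate thresholds on the controls, classify the patients, run the
# rater simulation and reliability analysis, the DTI subgroup contrast
# and the group comparisons, and bundle everything into one report.

# Recursively drop S3 classes so the bundle serializes as plain JSON.
strip_s3 <- function(x) {
  if (is.data.frame(x)) {
    class(x) <- "data.frame"
    return(x)
  }
  if (is.list(x)) return(lapply(unclass(x), strip_s3))
  x
}

#' Run the full HOD detection pipeline on a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param raters list of [rater_model()]s (default [default_raters()]
#'   seeded from the cohort seed).
#' @param mc_reps Monte-Carlo replicates for the normality screens.
#' @return named list (the report bundle): `config`, `subjects` (one row
#'   per subject per structural modality with asymmetry and
#'   classification), `calibration`, `exceedance_pct`, `dti`,
#'   `subgroup_contrast`, `rater` (kappa, diagnosis, false-positive and
#'   consensus rates per modality), `group_tests`, `truth`.
#' @export
run_hod_pipeline <- function(spec, raters = NULL, mc_reps = 2000L) {
  stopifnot(inherits(spec, "hod_cohort_spec"))
  if (is.null(raters)) raters <- default_raters(spec$seed + 1L)
  measured <- measure_cohort(spec)
  meta <- measured$meta
  str_df <- measured$structural

  # threshold calibration on controls, classification of everyone
  calibrations <- list()
  calls <- list()
  for (m in STRUCTURAL_MODALITIES) {
    rows <- str_df[str_df$modality == m, , drop = FALSE]
    ctrl <- rows$diff_percent[rows$role == "control"]
    if (length(ctrl) < 2L) next
    calib <- calibrate_threshold(ctrl, m)
    calibrations[[m]] <- calib
    for (i in seq_len(nrow(rows))) {
      a <- intensity_asymmetry(rows$left_mean[i], rows$right_mean[i],
                               rows$subject_id[i], m)
      mrow <- meta[meta$subject_id == rows$subject_id[i], , drop = FALSE][1, ]
      calls[[length(calls) + 1L]] <- classify_subject(a, calib, mrow)
    }
  }
  calls <- do.call(rbind, calls)
  exceedance <- vapply(names(calibrations), function(m) {
    if (any(calls$modality == m & calls$role == "patient")) {
      cohort_exceedance_rate(calls, m)
    } else {
      NA_real_
    }
  }, numeric(1))

  # rater-based analysis
  ratings <- simulate_raters(measured$truth, raters, meta)
  rater <- lapply(STRUCTURAL_MODALITIES, function(m) {
    list(
      modality = m,
      kappa = fleiss_kappa(ratings, m, subjects = meta),
      diagnosis_patients = diagnosis_rates(ratings, meta, m, "patient"),
      diagnosis_controls = diagnosis_rates(ratings, meta, m, "control"),
      false_positives = false_positive_rates(ratings, meta, m)
    )
  })
  names(rater) <- STRUCTURAL_MODALITIES

  # DTI subgroup contrast against the PD classification
  contrast <- NULL
  if (!is.null(measured$dti) && any(calls$modality == "PD")) {
    pd_calls <- calls[calls$modality == "PD" &
                        calls$subject_id %in% measured$dti$subject_id, ,
                      drop = FALSE]
    if (nrow(pd_calls)) contrast <- subgroup_contrast(measured$dti, pd_calls)
  }

  # control-cohort comparisons between modalities (paired within group)
  ctrl_wide <- lapply(STRUCTURAL_MODALITIES, function(m) {
    rows <- str_df[str_df$modality == m & str_df$role == "control", ]
    rows$diff_percent[order(rows$subject_id)]
  })
  names(ctrl_wide) <- STRUCTURAL_MODALITIES
  group_tests <- list()
  pairs <- list(c("PD", "T2"), c("PD", "FLAIR"), c("T2", "FLAIR"))
  for (p in pairs) {
    a <- ctrl_wide[[p[1]]]; b <- ctrl_wide[[p[2]]]
    if (length(a) >= 4L && length(a) == length(b)) {
      key <- paste0("controls_", p[1], "_vs_", p[2])
      group_tests[[key]] <- compare_groups(a, b, paired = TRUE,
                                           mc_reps = mc_reps,
                                           seed = spec$seed + 17L)
    }
  }

  list(
    config = list(
      n_patients = spec$n_patients, n_controls = spec$n_controls,
      hod_prevalence_in_patients = spec$hod_prevalence_in_patients,
      control_asymmetry_sd = as.list(spec$control_asymmetry_sd),
      patient_effect_distribution = spec$patient_effect_distribution,
      seed = spec$seed
    ),
    subjects = strip_s3(calls),
    calibration = lapply(calibrations, unclass),
    exceedance_pct = as.list(exceedance),
    dti = measured$dti,
    subgroup_contrast = strip_s3(contrast),
    rater = strip_s3(rater),
    group_tests = strip_s3(group_tests),
    truth = measured$truth
  )
}

#' Empty report bundle
#'
#' Shape-compatible report for a cohort with no subjects: zero subject
#' rows and explicit nulls for every calibration constant.
#' @return named list with the same top-level elements as
#'   [run_hod_pipeline()].
#' @export
empty_report <- function() {
  list(
    config = list(n_patients = 0L, n_controls = 0L),
    subjects = data.frame(
      subject_id = character(), modality = character(), role = character(),
      diff_percent = numeric(), exceeds_threshold = logical(),
      higher_side = character(), expected_side = character(),
      laterality_consistent = logical(), stringsAsFactors = FALSE
    ),
    calibration = setNames(
      rep(list(list(control_mean = NULL, control_sd = NULL, threshold = NULL,
                    n_controls = 0L)), length(STRUCTURAL_MODALITIES)),
      STRUCTURAL_MODALITIES
    ),
    exceedance_pct = NULL, dti = NULL, subgroup_contrast = NULL,
    rater = NULL, group_tests = NULL, truth = NULL
  )
}
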