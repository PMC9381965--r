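# Control-cohort calibration of the detection threshold and patient
# classification.
#
# The detection threshold for each structural modality is the control
# cohort's mean asymmetry plus 2.576 standard deviations (the "99%
# threshold"; 2.576 is the two-sided 99% normal quantile, so one-sided
# coverage of a normal control model is ~99.5%). A patient whose
# asymmetry strictly exceeds the threshold is quantitatively
# HOD-positive; if the higher-intensity side contradicts the side
# expected from the causative lesion the call is flagged as a
# laterality-inconsistent (false-positive) finding.

#' Calibrate the per-modality detection threshold
#'
#' @param control_diffs unsigned asymmetry indices (%) of the control
#'   cohort; at least 2 values, all nonnegative.
#' @param modality structural modality tag.
#' @param z quantile multiplier (default 2.576).
#' @return object of class `hod_calibration`: `control_mean`,
#'   `control_sd` (sample SD, n-1 denominator), `threshold = mean + z*sd`,
#'   `n_controls`, and a `degenerate` flag (with a warning) when the
#'   control SD is zero.
#' @export
calibrate_threshold <- function(control_diffs, modality, z = 2.576) {
  assert_modality(modality, STRUCTURAL_MODALITIES)
  control_diffs <- as.numeric(control_diffs)
  if (length(control_diffs) < 2L) {
    stop_hod("threshold calibration needs at least 2 control values",
             "hod_too_few_controls")
  }
  if (any(!is.finite(control_diffs)) || any(control_diffs < 0)) {
    stop_hod("control asymmetry indices must be finite and >= 0",
             "hod_invalid_controls")
  }
  m <- mean(control_diffs)
  s <- sd(control_diffs)
  degenerate <- s == 0
  if (degenerate) {
    warning("zero control SD: threshold degenerates to the control mean",
            call. = FALSE)
  }
  structure(
    list(modality = modality, control_mean = m, control_sd = s,
         threshold = m + z * s, z = z, n_controls = length(control_diffs),
         degenerate = degenerate),
    class = "hod_calibration"
  )
}

#' @export
print.hod_calibration <- function(x, ...) {
  cat(sprintf(
    "<hod_calibration> %s: mean %.3f%%, SD %.3f%% (n=%d) -> 99%% threshold %.3f%%%s\n",
    x$modality, x$control_mean, x$control_sd, x$n_controls, x$threshold,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Classify one subject against a calibrated threshold
#'
#' The comparison is strict: a difference exactly equal to the threshold
#' does not count as exceeding it. Laterality consistency is evaluated
#' only for exceeding calls on subjects with a defined expected side; a
#' positive call whose higher-intensity side is contralateral to the
#' expected side is a quantitative false positive.
#'
#' @param asym a [intensity_asymmetry()] result.
#' @param calib a [calibrate_threshold()] for the same modality.
#' @param meta a [subject_meta()] row for the subject.
#' @return one-row data.frame (class `hod_call`): `subject_id`,
#'   `modality`, `role`, `diff_percent`, `exceeds_threshold`,
#'   `higher_side`, `expected_side`, `laterality_consistent` (NA when not
#'   applicable).
#' @export
classify_subject <- function(asym, calib, meta) {
  stopifnot(inherits(asym, "hod_asymmetry"), inherits(calib, "hod_calibration"))
  if (!is.na(asym$modality) && asym$modality != calib$modality) {
    stop_hod(sprintf("modality mismatch: asymmetry is %s, calibration is %s",
                     asym$modality, calib$modality),
             "hod_modality_mismatch")
  }
  exceeds <- asym$diff_percent > calib$threshold
  expected <- meta$expected_hod_side
  lat <- if (exceeds && expected != "none") {
    asym$higher_side == expected
  } else {
    NA
  }
  out <- data.frame(
    subject_id = meta$subject_id, modality = calib$modality, role = meta$role,
    diff_percent = asym$diff_percent, exceeds_threshold = exceeds,
    higher_side = asym$higher_side, expected_side = expected,
    laterality_consistent = lat, stringsAsFactors = FALSE
  )
  class(out) <- c("hod_call", "data.frame")
  out
}

#' Fraction of patients exceeding the threshold
#'
#' The denominator counts patients with the modality available (i.e. with
#' a call present), mirroring the per-modality denominators of a cohort
#' with missing acquisitions.
#'
#' @param calls data.frame of [classify_subject()] rows.
#' @param modality structural modality tag.
#' @return percentage of patients exceeding, on the 0-100 scale.
#' @export
cohort_exceedance_rate <- function(calls, modality) {
  assert_modality(modality, STRUCTURAL_MODALITIES)
  rows <- calls[calls$modality == modality & calls$role == "patient", ,
                drop = FALSE]
  if (nrow(rows) == 0L) {
    stop_hod(sprintf("no patient calls for modality %s", modality),
             "hod_empty_calls")
  }
  100 * mean(rows$exceeds_threshold)
}
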