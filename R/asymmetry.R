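# The two normalized left/right percentage-difference statistics.
#
# Structural contrasts (PD/T2/FLAIR) use the unsigned index: the quadrant
# with the lower mean is the reference, so the index is always >= 0 and
# carries the higher side separately. FA/MD maps, where the expected HOD
# side is known from the causative lesion, use a signed index normalized
# by the expected side's mean, so FA decreases come out negative and MD
# increases positive. All percentages are carried as percentages
# (1.21 means 1.21%).

#' Unsigned intensity asymmetry index
#'
#' `100 * (mean_a - mean_b) / mean_b` with `mean_a` the higher and
#' `mean_b` the lower of the two anterior-quadrant means. Exactly equal
#' means yield `higher_side = "none"` and a difference of 0.
#'
#' @param left_mean,right_mean anterior-quadrant mean intensities; must be
#'   strictly positive (a nonpositive mean signals a segmentation failure).
#' @param subject_id,modality carried through into the result.
#' @return list of class `hod_asymmetry` with fields `mean_intensity_a`,
#'   `mean_intensity_b`, `higher_side`, `diff_percent`, plus the raw
#'   `left_mean`/`right_mean`.
#' @export
intensity_asymmetry <- function(left_mean, right_mean, subject_id = NA_character_,
                                modality = NA_character_) {
  if (!is_scalar_number(left_mean) || !is_scalar_number(right_mean) ||
      left_mean <= 0 || right_mean <= 0) {
    stop_hod("quadrant means must be positive scalars (segmentation failure?)",
             "hod_nonpositive_mean")
  }
  a <- max(left_mean, right_mean)
  b <- min(left_mean, right_mean)
  higher <- if (left_mean == right_mean) {
    "none"
  } else if (left_mean > right_mean) "left" else "right"
  structure(
    list(
      subject_id = subject_id, modality = modality,
      mean_intensity_a = a, mean_intensity_b = b,
      higher_side = higher, diff_percent = 100 * (a - b) / b,
      left_mean = left_mean, right_mean = right_mean
    ),
    class = "hod_asymmetry"
  )
}

#' Signed expected-side DTI asymmetry
#'
#' `100 * (mean_expected - mean_contralateral) / mean_expected`, the
#' percentage difference between the FA or MD mean on the side where HOD
#' is anticipated from the index lesion and the contralateral side,
#' normalized by the expected side. Negative for FA decreases, positive
#' for MD increases on the affected side.
#'
#' @param expected_side_mean ROI mean on the expected HOD side (> 0).
#' @param contralateral_mean ROI mean on the opposite side.
#' @param subject_id,map carried through (`map` is `"FA"` or `"MD"`).
#' @return list of class `hod_dti_asymmetry` with `signed_diff_percent`.
#' @export
dti_asymmetry <- function(expected_side_mean, contralateral_mean,
                          subject_id = NA_character_, map = NA_character_) {
  if (!is_scalar_number(expected_side_mean) || expected_side_mean <= 0) {
    stop_hod("expected-side mean must be a positive scalar",
             "hod_nonpositive_mean")
  }
  structure(
    list(
      subject_id = subject_id, map = map,
      mean_expected_side = expected_side_mean,
      mean_contralateral = contralateral_mean,
      signed_diff_percent =
        100 * (expected_side_mean - contralateral_mean) / expected_side_mean
    ),
    class = "hod_dti_asymmetry"
  )
}
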