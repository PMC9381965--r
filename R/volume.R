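#' Construct a volume
#'
#' A `hod_volume` is the carrier of all image arithmetic in the pipeline: a
#' 3-D scalar array with voxel spacing in mm, a modality tag and a subject
#' identifier. Axes follow the Right-Anterior-Superior (RAS) convention:
#' axis 1 runs left to right, axis 2 posterior to anterior, axis 3 inferior
#' to superior. Voxel coordinates are 0-based everywhere in this package;
#' slices are indexed along axis 3.
#'
#' @param data 3-D numeric array of intensities (arbitrary units).
#' @param spacing numeric length-3, voxel edge lengths `(dx, dy, dz)` in mm;
#'   all strictly positive.
#' @param modality one of `"PD"`, `"T2"`, `"FLAIR"`, `"FA"`, `"MD"`, `"T1"`.
#' @param subject_id subject identifier string.
#' @return object of class `hod_volume`.
#' @export
new_volume <- function(data, spacing, modality, subject_id = "unknown") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_hod("data must be a 3-D array", "hod_invalid_volume")
  }
  if (any(dim(data) < 1L)) {
    stop_hod("every axis must have length >= 1", "hod_invalid_volume")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_hod("spacing must be 3 positive numbers (mm)", "hod_invalid_volume")
  }
  assert_modality(modality)
  structure(
    list(
      data = data, spacing = spacing, modality = modality,
      subject_id = as.character(subject_id)
    ),
    class = "hod_volume"
  )
}

#' @export
print.hod_volume <- function(x, ...) {
  cat(sprintf(
    "<hod_volume> %s [%s]  %s voxels @ %s mm\n",
    x$subject_id, x$modality,
    paste(dim(x$data), collapse = "x"),
    paste(format(x$spacing, trim = TRUE), collapse = "x")
  ))
  invisible(x)
}

#' @export
dim.hod_volume <- function(x) dim(x$data)

#' Voxel volume in mm^3
#' @param volume a `hod_volume`.
#' @return scalar, `dx * dy * dz`.
#' @export
voxel_volume <- function(volume) prod(volume$spacing)

#' Mirror a volume left/right
#'
#' Reverses axis 1 (the left-right axis under the RAS convention). Used in
#' tests of mirror equivariance of the quadrant segmentation.
#'
#' @param volume a `hod_volume`.
#' @return the reflected `hod_volume`.
#' @export
mirror_volume <- function(volume) {
  volume$data <- volume$data[dim(volume$data)[1]:1, , , drop = FALSE]
  volume
}
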