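# Reading and writing of volumes, rating tables, landmark tables and the
# cohort-level result report. NIfTI-1 carries images; CSV carries tabular
# data; the summary report is JSON.

#' Read a volume from a NIfTI-1 file
#'
#' Loads a single 3-D volume and normalizes its axis order to
#' Right-Anterior-Superior so that "left" and "right" are unambiguous in
#' every downstream module. Voxel spacing is taken from the file header.
#'
#' @param path path to a `.nii` or `.nii.gz` file containing one 3-D volume.
#' @param modality modality tag to attach (not stored in NIfTI headers).
#' @param subject_id subject identifier; defaults to the file stem.
#' @return a [new_volume()] object.
#' @export
read_volume <- function(path, modality, subject_id = NULL) {
  if (!file.exists(path)) {
    stop_hod(sprintf("volume file not found: %s", path), "hod_missing_file")
  }
  img <- tryCatch(
    suppressWarnings(RNifti::readNifti(path)),
    error = function(e) {
      stop_hod(
        sprintf("unreadable NIfTI header in %s: %s", path, conditionMessage(e)),
        "hod_unreadable_header"
      )
    }
  )
  d <- dim(img)
  if (length(d) > 3L) {
    if (any(d[-(1:3)] > 1L)) {
      stop_hod(
        sprintf("%s holds a multi-timepoint image (dims %s); expected one 3-D volume",
                path, paste(d, collapse = "x")),
        "hod_multi_timepoint"
      )
    }
    img <- RNifti::asNifti(array(as.numeric(img), dim = d[1:3]), reference = img)
  }
  if (!identical(RNifti::orientation(img), "RAS")) {
    RNifti::orientation(img) <- "RAS"
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  new_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing,
             modality, subject_id)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param volume a `hod_volume`.
#' @param path destination file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "hod_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Create one rater decision record
#'
#' A rating is one rater's call on one subject and one structural modality:
#' HOD present or not, and if present on which side.
#'
#' @param rater_id,subject_id identifier strings.
#' @param modality `"PD"`, `"T2"` or `"FLAIR"`.
#' @param hod_present logical.
#' @param side `"left"`, `"right"`, or `"none"`; must be `"none"` exactly
#'   when `hod_present` is `FALSE`.
#' @return one-row data.frame with class `hod_ratings`.
#' @export
rating_record <- function(rater_id, subject_id, modality, hod_present, side) {
  r <- data.frame(
    rater_id = as.character(rater_id), subject_id = as.character(subject_id),
    modality = modality, hod_present = as.logical(hod_present), side = side,
    stringsAsFactors = FALSE
  )
  validate_ratings(r)
}

#' @rdname rating_record
#' @param ratings a data.frame of rating records.
#' @export
validate_ratings <- function(ratings) {
  needed <- c("rater_id", "subject_id", "modality", "hod_present", "side")
  missing_cols <- setdiff(needed, names(ratings))
  if (length(missing_cols)) {
    stop_hod(sprintf("ratings table lacks columns: %s",
                     paste(missing_cols, collapse = ", ")),
             "hod_invalid_ratings")
  }
  bad_mod <- !ratings$modality %in% STRUCTURAL_MODALITIES
  if (any(bad_mod)) {
    stop_hod(sprintf("row %d: unknown modality '%s'",
                     which(bad_mod)[1], ratings$modality[which(bad_mod)[1]]),
             "hod_invalid_ratings")
  }
  bad_side <- !ratings$side %in% SIDES
  if (any(bad_side)) {
    stop_hod(sprintf("row %d: unknown side '%s'",
                     which(bad_side)[1], ratings$side[which(bad_side)[1]]),
             "hod_invalid_ratings")
  }
  bad <- (ratings$hod_present & ratings$side == "none") |
    (!ratings$hod_present & ratings$side != "none")
  if (any(bad)) {
    stop_hod(sprintf(
      "row %d: hod_present=%s is inconsistent with side='%s'",
      which(bad)[1], ratings$hod_present[which(bad)[1]],
      ratings$side[which(bad)[1]]
    ), "hod_invalid_ratings")
  }
  class(ratings) <- c("hod_ratings", "data.frame")
  ratings
}

#' Read and write rater decision tables
#'
#' CSV with header `rater_id, subject_id, modality, hod_present, side`.
#' Every row is validated against the rating invariants (a positive call
#' must carry a side, a negative call must not); violations report the
#' offending row number. Row order is preserved.
#'
#' @param path CSV file path.
#' @return `read_ratings`: validated data.frame of records.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) {
    stop_hod(sprintf("ratings file not found: %s", path), "hod_missing_file")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$hod_present <- as.logical(df$hod_present)
  validate_ratings(df)
}

#' @rdname read_ratings
#' @param ratings validated ratings table.
#' @export
write_ratings <- function(ratings, path) {
  validate_ratings(as.data.frame(ratings))
  write.csv(ratings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write landmark tables
#'
#' One row per axial slice: `slice, fissure_x, fissure_y, sulcusL_x,
#' sulcusL_y, sulcusR_x, sulcusR_y`, with 0-based voxel coordinates
#' (possibly fractional). See [landmark_set()] for the geometric
#' invariants.
#'
#' @param path CSV file path.
#' @return `read_landmarks`: a `hod_landmarks` object (without medulla mask).
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) {
    stop_hod(sprintf("landmark file not found: %s", path), "hod_missing_file")
  }
  landmark_set(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_landmarks
#' @param landmarks a `hod_landmarks` object.
#' @export
write_landmarks <- function(landmarks, path) {
  write.csv(landmarks$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and re-read the cohort analysis report
#'
#' The report is the machine-readable end product of the pipeline: the
#' per-subject asymmetry table, per-modality calibration constants and
#' classifications, interrater agreement, rater rates and group test
#' results, serialized as JSON. An empty cohort yields a report with zero
#' subject rows and explicit nulls for the calibration constants.
#'
#' @param results named list as produced by [run_hod_pipeline()] (any
#'   subset of its elements is accepted).
#' @param path destination `.json` path.
#' @return `write_report`: `path` invisibly; `read_report`: the bundle.
#' @export
write_report <- function(results, path) {
  if (!is.list(results)) stop_hod("results must be a list", "hod_invalid_report")
  con <- tryCatch(file(path, open = "w"), error = function(e) {
    stop_hod(sprintf("cannot write report to %s", path), "hod_unwritable")
  })
  close(con)
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    stop_hod(sprintf("report not found: %s", path), "hod_missing_file")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}
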