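# Landmark-driven quadrant segmentation of the medulla oblongata.
#
# The medulla cross-section is divided by two lines drawn from three
# surface landmarks: the line joining the two posterolateral sulci
# (anterior vs posterior) and its perpendicular through the anterior
# median fissure (left vs right). The left- and right-anterior quadrants
# contain the inferior olivary nuclei and are the ROIs of the asymmetry
# analysis, pooled over an 8-mm axial slab.

#' Construct a landmark set
#'
#' @param points data.frame with one row per axial slice and columns
#'   `slice` (0-based slice index), `fissure_x`, `fissure_y` (anterior
#'   median fissure), `sulcusL_x`, `sulcusL_y`, `sulcusR_x`, `sulcusR_y`
#'   (posterolateral sulci). Coordinates are 0-based in-plane voxel
#'   indices, possibly fractional.
#' @param medulla_mask optional 3-D logical array marking the medulla
#'   cross-section; when absent, [build_quadrant_masks()] falls back to a
#'   disc of declared radius around the landmark centroid.
#'
#' Invariants checked per slice: the fissure lies anterior to the
#' sulcus-sulcus line, and the left sulcus lies on the anatomical left of
#' the fissure (smaller x under the RAS convention), the right sulcus on
#' its right.
#'
#' @return object of class `hod_landmarks`.
#' @export
landmark_set <- function(points, medulla_mask = NULL) {
  needed <- c("slice", "fissure_x", "fissure_y", "sulcusL_x", "sulcusL_y",
              "sulcusR_x", "sulcusR_y")
  missing_cols <- setdiff(needed, names(points))
  if (length(missing_cols)) {
    stop_hod(sprintf("landmark table lacks columns: %s",
                     paste(missing_cols, collapse = ", ")),
             "hod_invalid_landmarks")
  }
  ux <- points$sulcusR_x - points$sulcusL_x
  uy <- points$sulcusR_y - points$sulcusL_y
  if (any(ux == 0 & uy == 0)) {
    stop_hod("degenerate landmarks: sulci coincide", "hod_invalid_landmarks")
  }
  # anterior direction = +90 degree rotation of the sulcusL->sulcusR vector
  ant <- -uy * (points$fissure_x - points$sulcusL_x) +
    ux * (points$fissure_y - points$sulcusL_y)
  if (any(ant <= 0)) {
    stop_hod(
      sprintf("slice %d: fissure is not anterior to the sulcus-sulcus line",
              points$slice[which(ant <= 0)[1]]),
      "hod_invalid_landmarks"
    )
  }
  sl <- ux * (points$sulcusL_x - points$fissure_x) +
    uy * (points$sulcusL_y - points$fissure_y)
  sr <- ux * (points$sulcusR_x - points$fissure_x) +
    uy * (points$sulcusR_y - points$fissure_y)
  if (any(sl >= 0) || any(sr <= 0)) {
    stop_hod("sulci must flank the fissure (left sulcus left, right sulcus right)",
             "hod_invalid_landmarks")
  }
  structure(list(points = points[order(points$slice), , drop = FALSE],
                 medulla_mask = medulla_mask),
            class = "hod_landmarks")
}

#' Mirror a landmark set left/right
#'
#' Reflects in-plane x coordinates (`x -> nx - 1 - x`) and swaps the two
#' sulci, matching [mirror_volume()].
#'
#' @param landmarks a `hod_landmarks` object.
#' @param nx grid extent along the left-right axis.
#' @return mirrored `hod_landmarks`.
#' @export
mirror_landmarks <- function(landmarks, nx) {
  p <- landmarks$points
  q <- p
  q$fissure_x <- nx - 1 - p$fissure_x
  q$sulcusL_x <- nx - 1 - p$sulcusR_x
  q$sulcusL_y <- p$sulcusR_y
  q$sulcusR_x <- nx - 1 - p$sulcusL_x
  q$sulcusR_y <- p$sulcusL_y
  mask <- landmarks$medulla_mask
  if (!is.null(mask)) mask <- mask[dim(mask)[1]:1, , , drop = FALSE]
  landmark_set(q, mask)
}

#' Select the 8-mm analysis slab
#'
#' Returns the consecutive slice indices covering an 8-mm axial section
#' centred as symmetrically as possible on `olive_center_slice`: 4 slices
#' on 2-mm grids, 2 slices on 4-mm grids. When the slab cannot be centred
#' exactly, it is biased inferiorly (towards lower slice indices).
#'
#' @param volume a `hod_volume`; slice thickness is `spacing[3]`.
#' @param olive_center_slice 0-based slice index of the olive centre.
#' @param slab_mm slab thickness in mm (default 8).
#' @return integer vector of 0-based slice indices.
#' @export
select_slab <- function(volume, olive_center_slice, slab_mm = 8) {
  dz <- volume$spacing[3]
  n <- max(1L, as.integer(round(slab_mm / dz)))
  start <- as.integer(olive_center_slice) - as.integer(ceiling((n - 1) / 2))
  slab <- start + seq_len(n) - 1L
  nz <- dim(volume$data)[3]
  if (slab[1] < 0L || slab[n] > nz - 1L) {
    stop_hod(
      sprintf("slab [%d..%d] extends past volume slices [0..%d]",
              slab[1], slab[n], nz - 1L),
      "hod_slab_out_of_bounds"
    )
  }
  slab
}

#' Build left- and right-anterior quadrant masks
#'
#' On every slab slice the medulla cross-section is split by (i) the line
#' joining the two posterolateral sulci, separating anterior from
#' posterior, and (ii) the perpendicular to that line through the anterior
#' median fissure, separating left from right. The perpendicular (rather
#' than the image column axis) keeps the split correct under in-plane
#' rotation of the head. Voxels exactly on the midsagittal dividing line
#' are assigned to the left quadrant; voxels exactly on the sulcus line
#' count as anterior.
#'
#' @param volume a `hod_volume`.
#' @param landmarks a `hod_landmarks` with rows for every slab slice.
#' @param slab 0-based slice indices from [select_slab()].
#' @param medulla_radius_mm fallback disc radius (mm) used when the
#'   landmark set carries no medulla mask; the disc is centred on the
#'   centroid of the three landmarks.
#' @return object of class `hod_quadrant_mask`: logical arrays
#'   `left_anterior` and `right_anterior` on the volume grid (empty
#'   outside the slab), `slab_slices`, and voxel/volume bookkeeping.
#' @export
build_quadrant_masks <- function(volume, landmarks, slab,
                                 medulla_radius_mm = 9) {
  stopifnot(inherits(volume, "hod_volume"), inherits(landmarks, "hod_landmarks"))
  dims <- dim(volume$data)
  pts <- landmarks$points
  left <- array(FALSE, dims)
  right <- array(FALSE, dims)
  xs <- matrix(rep(0:(dims[1] - 1), dims[2]), dims[1], dims[2])
  ys <- matrix(rep(0:(dims[2] - 1), each = dims[1]), dims[1], dims[2])
  for (s in slab) {
    row <- pts[pts$slice == s, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop_hod(sprintf("no landmark row for slab slice %d", s),
               "hod_missing_landmark")
    }
    ux <- row$sulcusR_x - row$sulcusL_x
    uy <- row$sulcusR_y - row$sulcusL_y
    if (ux == 0 && uy == 0) {
      stop_hod(sprintf("slice %d: sulci coincide", s), "hod_invalid_landmarks")
    }
    # anterior = same side of the sulcus line as the fissure
    vx <- -uy; vy <- ux
    if (vx * (row$fissure_x - row$sulcusL_x) +
        vy * (row$fissure_y - row$sulcusL_y) < 0) {
      vx <- -vx; vy <- -vy
    }
    anterior <- vx * (xs - row$sulcusL_x) + vy * (ys - row$sulcusL_y) >= 0
    # signed coordinate along sulcusL->sulcusR through the fissure:
    # positive = anatomical right; ties (exactly 0) go left
    lr <- ux * (xs - row$fissure_x) + uy * (ys - row$fissure_y)
    if (!is.null(landmarks$medulla_mask)) {
      med <- landmarks$medulla_mask[, , s + 1L]
    } else {
      cx <- (row$fissure_x + row$sulcusL_x + row$sulcusR_x) / 3
      cy <- (row$fissure_y + row$sulcusL_y + row$sulcusR_y) / 3
      rx <- medulla_radius_mm / volume$spacing[1]
      ry <- medulla_radius_mm / volume$spacing[2]
      med <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
    }
    left[, , s + 1L] <- med & anterior & (lr <= 0)
    right[, , s + 1L] <- med & anterior & (lr > 0)
  }
  vox <- voxel_volume(volume)
  structure(
    list(
      left_anterior = left, right_anterior = right,
      slab_slices = as.integer(slab),
      voxel_count_left = sum(left), voxel_count_right = sum(right),
      volume_mm3_left = sum(left) * vox, volume_mm3_right = sum(right) * vox
    ),
    class = "hod_quadrant_mask"
  )
}

#' Mean intensity under a binary mask
#'
#' Arithmetic mean of the voxel intensities under the mask, pooled over
#' all slab slices (voxel-pooled, not a mean of per-slice means).
#'
#' @param volume a `hod_volume`.
#' @param mask logical array on the same grid.
#' @return scalar mean intensity.
#' @export
roi_mean <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask))) {
    stop_hod("mask grid does not match volume grid", "hod_grid_mismatch")
  }
  n <- sum(mask)
  if (n == 0) stop_hod("mask is empty", "hod_empty_mask")
  mean(volume$data[mask])
}
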