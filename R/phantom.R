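# Synthetic brainstem phantoms with known ground truth.
#
# The phantom is a cylindrical medulla oblongata containing two
# ellipsoidal inferior olivary nuclei (IONs) in the anterior quadrants.
# PD/T2/FLAIR volumes, FA/MD maps, landmark sets and ground-truth olive
# masks are generated on pre-aligned grids sharing one world coordinate
# frame (voxel centre of index i at (i + 0.5) * spacing mm). A planted
# unilateral HOD scales the affected olive's structural intensity up,
# enlarges it, lowers its FA and raises its MD; a signed residual
# asymmetry term scales one half of the medulla to emulate the
# physiological left/right differences seen in healthy controls.

#' Specify a brainstem phantom
#'
#' Defaults mirror the acquisition geometry of a dual-echo PD/T2 brainstem
#' protocol (240 mm field of view, 384 matrix cropped to a 60 mm region,
#' 2 mm slices -> 0.625 x 0.625 x 2 mm voxels), a FLAIR at 4 mm slice
#' thickness obtained by averaging pairs of 2 mm slices, and a 2 mm
#' isotropic DTI grid. The medulla is a 9 mm radius cylinder; each olive
#' is an ellipsoid with semi-axes 3 x 2 x 6 mm (right-left x
#' posterior-anterior x inferior-superior), matching the true ION's
#' roughly 6 mm width and 12 mm craniocaudal extent.
#'
#' @param grid_shape integer 3-vector, structural grid (default 96x96x24).
#' @param spacing structural voxel size in mm (default 0.625, 0.625, 2).
#' @param medulla_radius medulla cylinder radius, mm.
#' @param olive_center_left,olive_center_right olive centres as 0-based
#'   structural voxel coordinates `(x, y, z)`; defaults place them
#'   symmetrically 3 mm lateral and 4 mm anterior of the medulla axis.
#' @param olive_semiaxes ellipsoid semi-axes in mm.
#' @param background_intensity named per-modality tissue intensity for the
#'   structural contrasts (arbitrary units).
#' @param olive_contrast named per-modality relative hyperintensity of a
#'   normal ION over surrounding tissue (PD shows the ION best).
#' @param noise_sd named per-modality additive Gaussian noise SD, as a
#'   fraction of the background intensity (FA/MD: fraction of baseline).
#' @param hod_side `"left"`, `"right"` or `"none"`; side of the planted HOD.
#' @param hod_intensity_effect fractional intensity increase of the
#'   affected olive on PD/T2/FLAIR.
#' @param hod_enlargement fractional increase of the affected olive's
#'   semi-axes (hypertrophy).
#' @param fa_baseline,md_baseline FA (unitless) and MD (mm^2/s) of
#'   medullary tissue.
#' @param hod_fa_effect,hod_md_effect fractional FA decrease / MD increase
#'   in the affected olive.
#' @param residual_asymmetry named signed percentages (PD/T2/FLAIR): the
#'   half of the medulla on the higher side (positive = right) is scaled
#'   by `1 + |r|/100`, so the noiseless measured asymmetry index equals
#'   `|r|` exactly.
#' @param seed integer; the phantom is a pure function of the spec
#'   including this seed.
#' @return object of class `hod_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 24L),
                         spacing = c(0.625, 0.625, 2),
                         medulla_radius = 9,
                         olive_center_left = NULL,
                         olive_center_right = NULL,
                         olive_semiaxes = c(3, 2, 6),
                         background_intensity = c(PD = 100, T2 = 100, FLAIR = 100),
                         olive_contrast = c(PD = 0.3, T2 = 0.1, FLAIR = 0.1),
                         noise_sd = c(PD = 0.02, T2 = 0.02, FLAIR = 0.02,
                                      FA = 0.03, MD = 0.03),
                         hod_side = "none",
                         hod_intensity_effect = 0,
                         hod_enlargement = 0,
                         fa_baseline = 0.45,
                         md_baseline = 8e-4,
                         hod_fa_effect = 0.35,
                         hod_md_effect = 0.10,
                         residual_asymmetry = c(PD = 0, T2 = 0, FLAIR = 0),
                         seed = 1L) {
  assert_side(hod_side)
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(spacing) == 3L, all(spacing > 0))
  if (any(noise_sd < 0)) stop_hod("noise_sd must be >= 0", "hod_invalid_spec")
  if (fa_baseline < 0 || fa_baseline > 1) {
    stop_hod("fa_baseline must lie in [0, 1]", "hod_invalid_spec")
  }
  if (md_baseline <= 0) stop_hod("md_baseline must be > 0", "hod_invalid_spec")
  if (hod_intensity_effect < 0 || hod_enlargement < 0 ||
      hod_fa_effect < 0 || hod_fa_effect > 1 || hod_md_effect < 0) {
    stop_hod("HOD effect fractions out of range", "hod_invalid_spec")
  }
  fov <- grid_shape[1:2] * spacing[1:2]
  centre <- fov / 2
  if (is.null(olive_center_left) || is.null(olive_center_right)) {
    zc <- floor(grid_shape[3] / 2)  # integer centre slice
    # 4.5 mm lateral, 2.5 mm anterior of the medulla axis: keeps even a
    # hypertrophic (enlarged) olive clear of the midsagittal divider
    oy <- (centre[2] + 2.5) / spacing[2] - 0.5
    olive_center_left <- c((centre[1] - 4.5) / spacing[1] - 0.5, oy, zc)
    olive_center_right <- c((centre[1] + 4.5) / spacing[1] - 0.5, oy, zc)
  }
  spec <- structure(
    list(
      grid_shape = grid_shape, spacing = spacing,
      medulla_radius = medulla_radius,
      olive_center_left = olive_center_left,
      olive_center_right = olive_center_right,
      olive_semiaxes = as.numeric(olive_semiaxes),
      background_intensity = background_intensity,
      olive_contrast = olive_contrast, noise_sd = noise_sd,
      hod_side = hod_side, hod_intensity_effect = hod_intensity_effect,
      hod_enlargement = hod_enlargement,
      fa_baseline = fa_baseline, md_baseline = md_baseline,
      hod_fa_effect = hod_fa_effect, hod_md_effect = hod_md_effect,
      residual_asymmetry = residual_asymmetry,
      seed = as.integer(seed)
    ),
    class = "hod_phantom_spec"
  )
  validate_phantom_geometry(spec)
  spec
}

# Olives (including an enlarged one) must fit inside the medulla cylinder
# and the grid.
validate_phantom_geometry <- function(spec) {
  fov <- spec$grid_shape[1:2] * spec$spacing[1:2]
  if (any(fov / 2 - spec$medulla_radius < 0)) {
    stop_hod("medulla cylinder extends outside the grid", "hod_invalid_spec")
  }
  grow <- 1 + spec$hod_enlargement
  for (side in c("left", "right")) {
    ctr <- spec[[paste0("olive_center_", side)]]
    semi <- spec$olive_semiaxes *
      if (identical(spec$hod_side, side)) grow else 1
    world <- (ctr + 0.5) * spec$spacing
    centre <- c(spec$grid_shape[1:2] * spec$spacing[1:2] / 2, world[3])
    inplane <- sqrt(sum((world[1:2] - centre[1:2])^2))
    if (inplane + max(semi[1:2]) > spec$medulla_radius) {
      stop_hod(sprintf("%s olive extends outside the medulla cylinder", side),
               "hod_invalid_spec")
    }
    lo <- world - semi
    hi <- world + semi
    if (any(lo < 0) || any(hi > spec$grid_shape * spec$spacing)) {
      stop_hod(sprintf("%s olive extends outside the grid", side),
               "hod_invalid_spec")
    }
  }
  invisible(spec)
}

# World-coordinate meshes for a grid (voxel centres, mm).
grid_world <- function(shape, spacing) {
  list(
    x = (0:(shape[1] - 1) + 0.5) * spacing[1],
    y = (0:(shape[2] - 1) + 0.5) * spacing[2],
    z = (0:(shape[3] - 1) + 0.5) * spacing[3]
  )
}

ellipsoid_mask <- function(shape, spacing, centre_mm, semi_mm) {
  w <- grid_world(shape, spacing)
  dx2 <- ((w$x - centre_mm[1]) / semi_mm[1])^2
  dy2 <- ((w$y - centre_mm[2]) / semi_mm[2])^2
  dz2 <- ((w$z - centre_mm[3]) / semi_mm[3])^2
  arr <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  arr <= 1
}

cylinder_mask <- function(shape, spacing, centre_mm, radius_mm) {
  w <- grid_world(shape, spacing)
  d2 <- outer((w$x - centre_mm[1])^2, (w$y - centre_mm[2])^2, `+`)
  array(rep(d2 <= radius_mm^2, shape[3]), dim = shape)
}

# Landmarks for one grid: fissure at the anterior pole of the medulla,
# sulci at its lateral poles, identical on every slice.
phantom_landmarks <- function(shape, spacing, centre_mm, radius_mm,
                              medulla_mask) {
  to_vox <- function(mm, d) mm / d - 0.5
  pts <- data.frame(
    slice = 0:(shape[3] - 1),
    fissure_x = to_vox(centre_mm[1], spacing[1]),
    fissure_y = to_vox(centre_mm[2] + radius_mm, spacing[2]),
    sulcusL_x = to_vox(centre_mm[1] - radius_mm, spacing[1]),
    sulcusL_y = to_vox(centre_mm[2], spacing[2]),
    sulcusR_x = to_vox(centre_mm[1] + radius_mm, spacing[1]),
    sulcusR_y = to_vox(centre_mm[2], spacing[2])
  )
  landmark_set(pts, medulla_mask)
}

#' Generate a brainstem phantom
#'
#' Produces aligned PD, T2, FLAIR, FA and MD volumes, per-grid landmark
#' sets and a ground-truth record (olive masks, planted effects, olive
#' centre slices). Identical specs (including seed) give bit-identical
#' output.
#'
#' @param spec a [phantom_spec()].
#' @param subject_id subject identifier attached to all volumes.
#' @return object of class `hod_phantom`: list with elements `volumes`
#'   (named `hod_volume`s), `landmarks` (named `hod_landmarks` for the
#'   `structural`, `flair` and `dti` grids), and `truth`.
#' @export
generate_phantom <- function(spec, subject_id = "phantom") {
  stopifnot(inherits(spec, "hod_phantom_spec"))
  validate_phantom_geometry(spec)
  shape <- spec$grid_shape
  sp <- spec$spacing
  fov <- shape[1:2] * sp[1:2]
  centre <- fov / 2

  grids <- list(
    structural = list(shape = shape, spacing = sp),
    flair = list(shape = c(shape[1:2], shape[3] %/% 2L),
                 spacing = c(sp[1:2], 2 * sp[3])),
    dti = list(shape = c(as.integer(round(fov / 2)), shape[3]),
               spacing = c(2, 2, sp[3]))
  )

  grow <- 1 + spec$hod_enlargement
  semi <- list(
    left = spec$olive_semiaxes * if (spec$hod_side == "left") grow else 1,
    right = spec$olive_semiaxes * if (spec$hod_side == "right") grow else 1
  )
  centre_mm <- list(
    left = (spec$olive_center_left + 0.5) * sp,
    right = (spec$olive_center_right + 0.5) * sp
  )

  olive_masks <- lapply(grids, function(g) {
    list(
      left = ellipsoid_mask(g$shape, g$spacing, centre_mm$left, semi$left),
      right = ellipsoid_mask(g$shape, g$spacing, centre_mm$right, semi$right)
    )
  })
  medulla <- lapply(grids, function(g) {
    cylinder_mask(g$shape, g$spacing, centre, spec$medulla_radius)
  })
  landmarks <- lapply(names(grids), function(k) {
    g <- grids[[k]]
    phantom_landmarks(g$shape, g$spacing, centre, spec$medulla_radius,
                      medulla[[k]])
  })
  names(landmarks) <- names(grids)

  e <- spec$hod_intensity_effect
  side_factor <- function(side) {
    if (spec$hod_side == side && spec$hod_side != "none") 1 + e else 1
  }

  # right half of the medulla (world x above the midline); residual
  # asymmetry scales one half, never both
  right_half <- function(g, med) {
    w <- grid_world(g$shape, g$spacing)
    array(rep(w$x > centre[1], prod(g$shape[2:3])), dim = g$shape) & med
  }

  structural_image <- function(modality, g, med, olives) {
    b <- spec$background_intensity[[modality]]
    cst <- spec$olive_contrast[[modality]]
    img <- array(0.3 * b, dim = g$shape)
    img[med] <- b
    img[olives$left] <- b * (1 + cst) * side_factor("left")
    img[olives$right] <- b * (1 + cst) * side_factor("right")
    r <- spec$residual_asymmetry[[modality]]
    if (!is.null(r) && r != 0) {
      half <- right_half(g, med)
      if (r < 0) half <- med & !half
      img[half] <- img[half] * (1 + abs(r) / 100)
    }
    img
  }

  g1 <- grids$structural
  pd <- structural_image("PD", g1, medulla$structural, olive_masks$structural)
  t2 <- structural_image("T2", g1, medulla$structural, olive_masks$structural)
  # FLAIR acquired at doubled slice thickness: average consecutive pairs
  # of thin slices of the noiseless FLAIR contrast
  fl_thin <- structural_image("FLAIR", g1, medulla$structural,
                              olive_masks$structural)
  nz2 <- grids$flair$shape[3]
  fl <- (fl_thin[, , 2 * seq_len(nz2) - 1, drop = FALSE] +
           fl_thin[, , 2 * seq_len(nz2), drop = FALSE]) / 2

  gd <- grids$dti
  dti_factor <- function(map) {
    eff <- if (map == "FA") -spec$hod_fa_effect else spec$hod_md_effect
    function(side) {
      if (spec$hod_side == side && spec$hod_side != "none") 1 + eff else 1
    }
  }
  dti_image <- function(map, baseline, outside) {
    f <- dti_factor(map)
    img <- array(outside, dim = gd$shape)
    img[medulla$dti] <- baseline
    img[olive_masks$dti$left] <- baseline * f("left")
    img[olive_masks$dti$right] <- baseline * f("right")
    img
  }
  fa <- dti_image("FA", spec$fa_baseline, 0.15)
  md <- dti_image("MD", spec$md_baseline, 2.5e-3)

  with_seed(spec$seed, {
    add_noise <- function(img, modality, scale) {
      s <- spec$noise_sd[[modality]] %||% 0
      if (s > 0) img + array(rnorm(length(img), 0, s * scale), dim(img)) else img
    }
    pd <- add_noise(pd, "PD", spec$background_intensity[["PD"]])
    t2 <- add_noise(t2, "T2", spec$background_intensity[["T2"]])
    fl <- add_noise(fl, "FLAIR", spec$background_intensity[["FLAIR"]])
    fa <- add_noise(fa, "FA", spec$fa_baseline)
    md <- add_noise(md, "MD", spec$md_baseline)
  })

  volumes <- list(
    PD = new_volume(pd, g1$spacing, "PD", subject_id),
    T2 = new_volume(t2, g1$spacing, "T2", subject_id),
    FLAIR = new_volume(fl, grids$flair$spacing, "FLAIR", subject_id),
    FA = new_volume(fa, gd$spacing, "FA", subject_id),
    MD = new_volume(md, gd$spacing, "MD", subject_id)
  )

  zc <- spec$olive_center_left[3]
  truth <- list(
    subject_id = subject_id,
    hod_side = spec$hod_side,
    hod_intensity_effect = e,
    hod_enlargement = spec$hod_enlargement,
    hod_fa_effect = spec$hod_fa_effect,
    hod_md_effect = spec$hod_md_effect,
    residual_asymmetry = spec$residual_asymmetry,
    olive_masks = olive_masks,
    medulla_masks = medulla,
    center_slice = list(
      structural = as.integer(zc),
      # the thick slice whose 4-mm extent contains the olive centre
      flair = as.integer(((zc + 0.5) * sp[3]) %/% grids$flair$spacing[3]),
      dti = as.integer(zc)
    ),
    spec = spec
  )
  structure(list(volumes = volumes, landmarks = landmarks, truth = truth),
            class = "hod_phantom")
}

#' Grid family of a modality
#' @param modality modality tag.
#' @return `"structural"`, `"flair"` or `"dti"`.
#' @export
modality_grid <- function(modality) {
  switch(assert_modality(modality, c("PD", "T2", "FLAIR", "FA", "MD")),
         PD = "structural", T2 = "structural", FLAIR = "flair",
         FA = "dti", MD = "dti")
}

#' Measure the anterior-quadrant means of a phantom
#'
#' Runs the quadrant segmentation on one modality of a phantom: selects
#' the 8-mm slab around the ground-truth olive centre, builds the
#' left/right anterior quadrant masks from the landmark set, and returns
#' the pooled ROI means.
#'
#' @param phantom a [generate_phantom()] result.
#' @param modality modality to measure.
#' @return list with `left_mean`, `right_mean`, `masks` (the
#'   `hod_quadrant_mask`) and `slab`.
#' @export
measure_phantom <- function(phantom, modality) {
  stopifnot(inherits(phantom, "hod_phantom"))
  key <- modality_grid(modality)
  vol <- phantom$volumes[[modality]]
  slab <- select_slab(vol, phantom$truth$center_slice[[key]])
  masks <- build_quadrant_masks(vol, phantom$landmarks[[key]], slab)
  list(
    left_mean = roi_mean(vol, masks$left_anterior),
    right_mean = roi_mean(vol, masks$right_anterior),
    masks = masks, slab = slab
  )
}

#' Noiseless expected asymmetry of a phantom spec
#'
#' Predicts the asymmetry the pipeline will measure on a phantom by
#' regenerating it with all noise switched off and running the
#' segmentation, i.e. the planted effect after dilution by the
#' olive-to-quadrant voxel ratio. For structural modalities the unsigned
#' index is returned; for FA/MD the signed expected-side difference
#' (relative to `expected_side`).
#'
#' @param spec a [phantom_spec()].
#' @param modality modality tag.
#' @param expected_side side used as the reference for FA/MD (defaults to
#'   the planted side).
#' @return expected percentage difference.
#' @export
predicted_asymmetry <- function(spec, modality, expected_side = spec$hod_side) {
  spec$noise_sd[] <- 0
  ph <- generate_phantom(spec, "noiseless")
  m <- measure_phantom(ph, modality)
  if (modality %in% STRUCTURAL_MODALITIES) {
    intensity_asymmetry(m$left_mean, m$right_mean)$diff_percent
  } else {
    assert_side(expected_side)
    if (expected_side == "none") {
      stop_hod("expected_side must be left or right for FA/MD",
               "hod_invalid_side")
    }
    exp_mean <- if (expected_side == "left") m$left_mean else m$right_mean
    ctr_mean <- if (expected_side == "left") m$right_mean else m$left_mean
    dti_asymmetry(exp_mean, ctr_mean)$signed_diff_percent
  }
}
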