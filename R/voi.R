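#' Volume-of-interest mask
#'
#' A boolean 3D mask on a [pet_grid()], with its provenance (how it was
#' constructed) and derived volume in mL.
#'
#' @param mask Logical 3D array matching the grid dimensions.
#' @param grid A `pet_grid`.
#' @param provenance One of `"contour"`, `"spheres"`, `"idif"`, `"region"`.
#' @return A list of class `voi_mask` with elements `mask`, `grid`,
#'   `provenance`.
#' @export
voi_mask <- function(mask, grid, provenance = "region") {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!identical(dim(mask), grid$dim)) {
    stop("mask shape does not match grid shape")
  }
  structure(list(mask = mask, grid = grid, provenance = provenance),
            class = "voi_mask")
}

#' @rdname voi_mask
#' @param voi A `voi_mask`.
#' @return `voi_volume_mL()`: voxel count times voxel volume, in mL.
#' @export
voi_volume_mL <- function(voi) {
  sum(voi$mask) * voxel_volume_mL(voi$grid)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s: %d voxels, %.2f mL\n",
              x$provenance, sum(x$mask), voi_volume_mL(x)))
  invisible(x)
}

#' Axial level at a fraction of the lower-leg length
#'
#' World z-coordinate at `fraction` of the distance from the distal end of
#' the medial malleolus to the knee joint space. The muscle VOI is placed
#' at 60% of the lower-leg length, the single-slice level shown to best
#' represent calf muscle volume.
#'
#' @param malleolus_z_mm,knee_z_mm Axial landmarks (mm), malleolus below
#'   knee.
#' @param fraction Fraction of the lower-leg length, in \[0, 1\].
#' @return z in mm: `malleolus_z_mm + fraction * (knee_z_mm - malleolus_z_mm)`.
#' @examples
#' lower_leg_level(0, 380)   # 228 mm
#' @export
lower_leg_level <- function(malleolus_z_mm, knee_z_mm, fraction = 0.6) {
  if (malleolus_z_mm >= knee_z_mm) {
    stop("`malleolus_z_mm` must be below `knee_z_mm` (inverted landmarks?)")
  }
  if (fraction < 0 || fraction > 1) stop("`fraction` must lie in [0, 1]")
  malleolus_z_mm + fraction * (knee_z_mm - malleolus_z_mm)
}

# Binary dilation by a Euclidean ball of `margin_mm` in world mm, honouring
# anisotropic voxels. FFT convolution with the ball indicator: a voxel is in
# the dilation iff some true voxel lies within the ball, i.e. the
# correlation count is >= 1 (tested against 0.5 for float tolerance).
dilate_ball_mm <- function(mask, grid, margin_mm) {
  if (margin_mm < 0) stop("margin must be non-negative")
  r <- floor(margin_mm / grid$voxel_mm)   # kernel half-extent in voxels
  if (all(r == 0) && margin_mm < min(grid$voxel_mm)) return(mask)
  kd <- 2L * as.integer(r) + 1L
  off <- lapply(1:3, function(a) ((seq_len(kd[a]) - 1L) - r[a]) * grid$voxel_mm[a])
  d2 <- outer(outer(off[[1]]^2, off[[2]]^2, `+`), off[[3]]^2, `+`)
  kern <- d2 <= margin_mm^2 + 1e-9
  nd <- dim(mask) + kd - 1L
  A <- array(0, nd); K <- array(0, nd)
  A[seq_len(dim(mask)[1]), seq_len(dim(mask)[2]), seq_len(dim(mask)[3])] <-
    as.numeric(mask)
  K[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- as.numeric(kern)
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) /
    prod(nd)
  # full convolution index shift: output voxel i corresponds to conv index
  # i + r (kernel centre offset)
  out <- conv[r[1] + seq_len(dim(mask)[1]),
              r[2] + seq_len(dim(mask)[2]),
              r[3] + seq_len(dim(mask)[3])]
  out > 0.5
}

#' Bone exclusion zone
#'
#' Expands the bone mask by a safety margin: every voxel whose centre lies
#' within `margin_mm` (Euclidean, world mm) of any bone-voxel centre,
#' union the bone itself. The default 20 mm margin standardises delineation
#' around the tibia and fibula and guards against patient motion.
#'
#' @param bone A [voi_mask()] marking bone voxels.
#' @param margin_mm Margin in mm, >= 0.
#' @return A `voi_mask` of the exclusion zone.
#' @export
bone_exclusion_zone <- function(bone, margin_mm = 20) {
  if (!inherits(bone, "voi_mask")) stop("`bone` must be a `voi_mask`")
  if (margin_mm < 0) stop("`margin_mm` must be non-negative")
  if (margin_mm == 0) return(voi_mask(bone$mask, bone$grid, "region"))
  voi_mask(dilate_ball_mm(bone$mask, bone$grid, margin_mm), bone$grid,
           "region")
}

# slice (1-based) whose axial extent [k-1, k) * dz contains z_mm
slice_index_of <- function(z_mm, grid) {
  k <- floor(z_mm / grid$voxel_mm[3]) + 1L
  if (k < 1L || k > grid$dim[3]) stop("axial level outside the volume")
  as.integer(k)
}

#' Contour-based muscle VOI
#'
#' Selects the posterior-compartment muscle label in `n_slices` consecutive
#' axial slices around the level slice, minus the bone exclusion zone —
#' the in-silico counterpart of manually contouring all muscle tissue
#' posterior to the bones in ten 1.5-mm slices at the 60% level. With the
#' default `n_slices = 10` the stack runs from 4 slices below to 5 above
#' the slice containing the level (an even count cannot be symmetric about
#' one slice; the stack is centred within half a slice).
#'
#' @param labels Integer label array (see [phantom_labels()]).
#' @param grid The `pet_grid` of `labels`.
#' @param level_z_mm Axial level (mm), e.g. from [lower_leg_level()].
#' @param n_slices Number of consecutive axial slices.
#' @param bone_zone A `voi_mask` to exclude (e.g. [bone_exclusion_zone()]);
#'   `NULL` for no exclusion.
#' @param label Label code to contour (default: posterior compartment).
#' @return A `voi_mask` with provenance `"contour"`.
#' @export
muscle_contour_voi <- function(labels, grid, level_z_mm, n_slices = 10,
                               bone_zone = NULL,
                               label = phantom_label_codes[["posterior"]]) {
  if (n_slices < 1) stop("`n_slices` must be at least 1")
  lev <- slice_index_of(level_z_mm, grid)
  lo <- lev - ceiling(n_slices / 2) + 1L
  hi <- lev + floor(n_slices / 2)
  if (lo < 1L || hi > grid$dim[3]) {
    stop("slice stack does not fit in the volume")
  }
  m <- array(FALSE, dim = grid$dim)
  m[, , lo:hi] <- labels[, , lo:hi] == label
  if (!is.null(bone_zone)) {
    if (!same_grid(grid, bone_zone$grid)) stop("bone zone grid mismatch")
    m <- m & !bone_zone$mask
  }
  if (!any(m)) stop("contour VOI is empty after bone exclusion")
  voi_mask(m, grid, "contour")
}

#' Sphere specification
#'
#' @param center_mm Sphere centre `(x, y, z)` in world mm.
#' @param radius_mm Radius in mm (> 0); default 7.5, the standardised
#'   sphere size (two such spheres total 3.5 mL).
#' @return A list of class `sphere_spec`.
#' @export
sphere_spec <- function(center_mm, radius_mm = 7.5) {
  if (length(center_mm) != 3L) stop("`center_mm` must be (x, y, z)")
  if (radius_mm <= 0) stop("`radius_mm` must be positive")
  structure(list(center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm),
            class = "sphere_spec")
}

#' Sphere-based VOI
#'
#' Voxelises a union of spheres: a voxel belongs to the VOI iff its centre
#' lies within the radius of any sphere; overlapping spheres are unioned
#' without double counting. The standardised muscle VOI uses two 7.5-mm
#' spheres placed medially and laterally in the posterior compartment.
#'
#' @param spheres A list of [sphere_spec()] objects (a single spec is
#'   accepted).
#' @param grid A [pet_grid()].
#' @return A `voi_mask` with provenance `"spheres"`.
#' @export
sphere_voi <- function(spheres, grid) {
  if (inherits(spheres, "sphere_spec")) spheres <- list(spheres)
  if (length(spheres) == 0L) stop("no spheres given")
  ext <- grid$dim * grid$voxel_mm
  m <- array(FALSE, dim = grid$dim)
  x <- axis_centers_mm(grid, 1)
  y <- axis_centers_mm(grid, 2)
  z <- axis_centers_mm(grid, 3)
  for (s in spheres) {
    if (!inherits(s, "sphere_spec")) stop("spheres must be `sphere_spec`s")
    if (any(s$center_mm < 0) || any(s$center_mm > ext)) {
      stop("sphere centre lies outside the grid")
    }
    dx2 <- (x - s$center_mm[1])^2
    dy2 <- (y - s$center_mm[2])^2
    dz2 <- (z - s$center_mm[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    m <- m | (d2 <= s$radius_mm^2 + 1e-9)
  }
  voi_mask(m, grid, "spheres")
}

#' Default sphere placement in the posterior compartment
#'
#' Automated stand-in for manual medial/lateral sphere placement: centres
#' offset left/right (x) from the posterior-compartment centroid in the
#' level slice, at the level-slice z. The virtual-rater study jitters these
#' centres to emulate manual placement variability.
#'
#' @param labels Label array.
#' @param grid The label grid.
#' @param level_z_mm Axial level (mm).
#' @param offset_mm Medial/lateral centre offset from the centroid (mm).
#' @param radius_mm Sphere radius (mm).
#' @param label Compartment label code.
#' @return List of two [sphere_spec()]s.
#' @export
default_sphere_centers <- function(labels, grid, level_z_mm, offset_mm = 15,
                                   radius_mm = 7.5,
                                   label = phantom_label_codes[["posterior"]]) {
  lev <- slice_index_of(level_z_mm, grid)
  sl <- labels[, , lev] == label
  if (!any(sl)) stop("posterior compartment empty at the level slice")
  idx <- which(sl, arr.ind = TRUE)
  cx <- mean((idx[, 1] - 0.5) * grid$voxel_mm[1])
  cy <- mean((idx[, 2] - 0.5) * grid$voxel_mm[2])
  cz <- (lev - 0.5) * grid$voxel_mm[3]
  list(
    sphere_spec(c(cx - offset_mm, cy, cz), radius_mm),
    sphere_spec(c(cx + offset_mm, cy, cz), radius_mm)
  )
}

# one-voxel-step morphological jitter used by the virtual-rater study:
# steps > 0 dilates, < 0 erodes, by |steps| single-voxel ball steps
morph_jitter <- function(voi, steps) {
  if (steps == 0) return(voi)
  m <- voi$mask
  r <- min(voi$grid$voxel_mm) + 1e-6
  for (i in seq_len(abs(steps))) {
    m <- if (steps > 0) {
      dilate_ball_mm(m, voi$grid, r)
    } else {
      !dilate_ball_mm(!m, voi$grid, r)
    }
  }
  if (!any(m)) stop("erosion emptied the VOI")
  voi_mask(m, voi$grid, voi$provenance)
}

#' Label region as a VOI mask
#'
#' Convenience accessor: the set of voxels carrying a given label code,
#' e.g. the artery search region for IDIF extraction.
#'
#' @param labels Label array.
#' @param grid The label grid.
#' @param label Label code or name from [phantom_label_codes].
#' @return A `voi_mask`.
#' @export
label_voi <- function(labels, grid, label) {
  if (is.character(label)) label <- phantom_label_codes[[label]]
  m <- labels == label
  if (!any(m)) stop("label not present in the volume")
  voi_mask(m, grid, "region")
}
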