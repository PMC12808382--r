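#' Peak (first-pass) frame of a region
#'
#' The frame in which the mean concentration over the search region is
#' highest — the frame where the blood pool is best visible during the
#' first pass of the bolus. Ties resolve to the earliest frame.
#'
#' @param scan A `pet_scan`.
#' @param region A non-empty [voi_mask()] (the artery search region).
#' @return 1-based frame index.
#' @export
find_peak_frame <- function(scan, region) {
  tac <- extract_tac(scan, region, role = "input")
  which.max(tac$value)
}

#' Axial start plane a fixed distance distal to the arterial bifurcation
#'
#' Returns the 1-based index of the axial plane containing the world
#' coordinate `bifurcation_z_mm - offset_mm` (a coordinate on a plane
#' boundary belongs to the upper plane). Distal means toward the foot,
#' i.e. decreasing z. The default 30 mm offset standardises the sampling
#' location relative to the common femoral artery bifurcation.
#'
#' @param bifurcation_z_mm Bifurcation z (world mm).
#' @param grid A [pet_grid()].
#' @param offset_mm Distal offset in mm.
#' @return 1-based axial plane index.
#' @export
locate_start_plane <- function(bifurcation_z_mm, grid, offset_mm = 30) {
  target <- bifurcation_z_mm - offset_mm
  if (target < 0 || target >= grid$dim[3] * grid$voxel_mm[3]) {
    stop("target plane lies outside the volume")
  }
  slice_index_of(target, grid)
}

#' Extract the image-derived input function
#'
#' Applies the arterial voxel-selection rule: at the peak (first-pass)
#' frame, in each of `n_planes` consecutive axial planes starting at
#' `start_plane`, the `n_vox` highest-intensity voxels inside the search
#' region are selected (ties broken by lexicographic (x, y) voxel index so
#' the selection is deterministic); the union mask is then applied
#' unchanged to every frame and the unweighted per-frame mean is the IDIF.
#' No partial-volume or spill-over correction is applied.
#'
#' @param scan A `pet_scan`.
#' @param region Artery search [voi_mask()].
#' @param start_plane 1-based first axial plane (e.g. from
#'   [locate_start_plane()]).
#' @param n_vox Voxels selected per plane (default 4).
#' @param n_planes Number of consecutive planes (default 10).
#' @param peak_frame Frame used for selection; defaults to
#'   [find_peak_frame()].
#' @return A list of class `idif_selection`: `voi` (the selection
#'   `voi_mask`, provenance `"idif"`), `tac` (the IDIF as a `pet_tac` with
#'   role `"input"`), `start_plane`, `peak_frame`, `n_vox`, `n_planes`.
#' @export
extract_idif <- function(scan, region, start_plane, n_vox = 4,
                         n_planes = 10, peak_frame = NULL) {
  if (!inherits(region, "voi_mask")) stop("`region` must be a `voi_mask`")
  if (!same_grid(scan$grid, region$grid)) stop("region grid mismatch")
  nz <- scan$grid$dim[3]
  planes <- start_plane + seq_len(n_planes) - 1L
  if (start_plane < 1L || max(planes) > nz) {
    stop("plane range extends outside the volume")
  }
  if (is.null(peak_frame)) peak_frame <- find_peak_frame(scan, region)

  sel <- array(FALSE, dim = scan$grid$dim)
  peak_vol <- array(scan$data[, , , peak_frame], dim = scan$grid$dim)
  for (k in planes) {
    plane_mask <- matrix(region$mask[, , k], scan$grid$dim[1],
                         scan$grid$dim[2])
    in_region <- which(plane_mask, arr.ind = TRUE)
    if (nrow(in_region) < n_vox) {
      stop(sprintf("plane %d holds only %d candidate voxels (need %d)",
                   k, nrow(in_region), n_vox))
    }
    v <- peak_vol[cbind(in_region, k)]
    ord <- order(-v, in_region[, 1], in_region[, 2])
    top <- in_region[ord[seq_len(n_vox)], , drop = FALSE]
    sel[cbind(top, k)] <- TRUE
  }
  voi <- voi_mask(sel, scan$grid, "idif")
  tac <- extract_tac(scan, voi, role = "input")
  structure(
    list(voi = voi, tac = tac, start_plane = start_plane,
         peak_frame = peak_frame, n_vox = n_vox, n_planes = n_planes),
    class = "idif_selection"
  )
}

#' @export
print.idif_selection <- function(x, ...) {
  cat(sprintf(
    "<idif_selection> %d voxels (%d planes x %d), peak frame %d, start plane %d\n",
    sum(x$voi$mask), x$n_planes, x$n_vox, x$peak_frame, x$start_plane
  ))
  invisible(x)
}
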