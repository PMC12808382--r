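#' Metric voxel grid
#'
#' Describes the voxel lattice shared by the dynamic image, the label volume
#' and every VOI mask. Voxel indices are 1-based (R convention); the world
#' coordinate of the centre of voxel `(i, j, k)` is
#' `((i - 0.5) dx, (j - 0.5) dy, (k - 0.5) dz)` mm from the volume origin.
#' The third axis is axial; z increases from the foot towards the abdomen,
#' so "distal" means decreasing z.
#'
#' @param dim Integer vector `(nx, ny, nz)`.
#' @param voxel_mm Numeric vector `(dx, dy, dz)` of voxel edge lengths in mm
#'   (default 1.65 x 1.65 x 1.5, the reconstruction grid of the lower-leg
#'   protocol).
#' @return A list of class `pet_grid` with elements `dim` and `voxel_mm`.
#' @examples
#' pet_grid(c(64, 64, 48))
#' @export
pet_grid <- function(dim, voxel_mm = c(1.65, 1.65, 1.5)) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L)) {
    stop("`dim` must be three positive integers")
  }
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0)) {
    stop("`voxel_mm` must be three positive edge lengths")
  }
  structure(list(dim = dim, voxel_mm = as.numeric(voxel_mm)),
            class = "pet_grid")
}

#' @export
print.pet_grid <- function(x, ...) {
  cat(sprintf("<pet_grid> %d x %d x %d voxels of %g x %g x %g mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  invisible(x)
}

#' @rdname pet_grid
#' @param grid A `pet_grid`.
#' @return `voxel_volume_mL()`: the volume of one voxel in mL.
#' @export
voxel_volume_mL <- function(grid) {
  prod(grid$voxel_mm) / 1000
}

# World-coordinate centres along one axis (mm).
axis_centers_mm <- function(grid, axis) {
  (seq_len(grid$dim[axis]) - 0.5) * grid$voxel_mm[axis]
}

same_grid <- function(a, b) {
  identical(a$dim, b$dim) && isTRUE(all.equal(a$voxel_mm, b$voxel_mm))
}
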