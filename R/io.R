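#' Write a simulated scan to disk
#'
#' Serialises a `pet_scan` to the standard on-disk layout: the 4D dynamic
#' volume and the 3D label volume as NIfTI (voxel sizes in the header), the
#' framing scheme as a JSON sidecar next to the dynamic volume, and the
#' ground-truth kinetics as CSV.
#'
#' @param scan A `pet_scan`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written (`dynamic`,
#'   `labels`, `framing`, `ground_truth`).
#' @export
write_scan_nifti <- function(scan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    dynamic = file.path(dir, "dynamic.nii.gz"),
    labels = file.path(dir, "labels.nii.gz"),
    framing = file.path(dir, "framing.json"),
    ground_truth = file.path(dir, "ground_truth.csv")
  )
  vx <- scan$grid$voxel_mm
  dyn <- RNifti::asNifti(structure(scan$data, pixdim = c(vx, 1)),
                         datatype = "float")
  RNifti::writeNifti(dyn, paths$dynamic)
  lab <- RNifti::asNifti(
    structure(array(as.integer(scan$labels), dim = scan$grid$dim),
              pixdim = vx),
    datatype = "uint8"
  )
  RNifti::writeNifti(lab, paths$labels)
  write_framing_json(scan$framing, paths$framing,
                     decay_corrected = scan$decay_corrected,
                     half_life_s = if (is.null(scan$decay)) NA_real_ else
                       scan$decay$half_life_s)
  kin <- scan$ground_truth$params$kinetics
  utils::write.csv(
    data.frame(label = kin$tissue, k1 = kin$k1, k2 = kin$k2,
               delay_s = kin$delay_s),
    paths$ground_truth, row.names = FALSE
  )
  invisible(paths)
}

#' Read a dynamic scan from disk
#'
#' Loads a 4D NIfTI volume, its JSON framing sidecar and (optionally) a
#' label volume into the in-memory structure the analysis functions
#' consume. Voxel sizes are taken from the NIfTI header.
#'
#' @param dynamic_path Path to the 4D NIfTI.
#' @param framing_path Path to the JSON sidecar; defaults to
#'   `framing.json` next to the dynamic volume.
#' @param labels_path Optional path to a 3D label NIfTI on the same grid.
#' @return A list of class `pet_scan` (without ground truth or phantom
#'   geometry).
#' @export
read_scan_nifti <- function(dynamic_path,
                            framing_path = file.path(dirname(dynamic_path),
                                                     "framing.json"),
                            labels_path = NULL) {
  img <- RNifti::readNifti(dynamic_path)
  d <- dim(img)
  if (length(d) != 4L) stop("dynamic volume must be 4D")
  vx <- RNifti::pixdim(img)[1:3]
  side <- read_framing_json(framing_path)
  if (n_frames(side$framing) != d[4]) {
    stop("sidecar frame count does not match the 4th image dimension")
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- RNifti::readNifti(labels_path)
    if (!identical(dim(lab)[1:3], d[1:3])) stop("label grid mismatch")
    labels <- array(as.integer(lab), dim = d[1:3])
  }
  structure(
    list(data = array(as.numeric(img), dim = d),
         grid = pet_grid(d[1:3], vx),
         framing = side$framing, labels = labels,
         decay = if (is.finite(side$half_life_s)) decay_spec(side$half_life_s) else NULL,
         decay_corrected = side$decay_corrected,
         ground_truth = NULL, phantom = NULL, seed = NULL),
    class = "pet_scan"
  )
}

#' Write a VOI mask as NIfTI
#'
#' @param voi A [voi_mask()].
#' @param path Output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_voi_nifti <- function(voi, path) {
  img <- RNifti::asNifti(
    structure(array(as.integer(voi$mask), dim = voi$grid$dim),
              pixdim = voi$grid$voxel_mm),
    datatype = "uint8"
  )
  RNifti::writeNifti(img, path)
  invisible(path)
}
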