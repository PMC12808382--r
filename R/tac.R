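#' Extract a time-activity curve from a VOI
#'
#' Per frame, the unweighted mean concentration over the mask voxels — the
#' volume-normalised (intensive) uptake, so the result does not scale with
#' VOI size and keeps K1's units well defined.
#'
#' @param scan A `pet_scan` (see [simulate_dynamic_scan()]) or any list
#'   with `data` (4D array), `grid` and `framing`.
#' @param voi A [voi_mask()] on the same grid, non-empty.
#' @param role `"tissue"` or `"input"`.
#' @return A tibble of class `pet_tac` with columns `frame`, `mid_time_s`,
#'   `duration_s`, `value` (kBq/mL), and attributes `role` and `volume_mL`.
#' @export
extract_tac <- function(scan, voi, role = c("tissue", "input")) {
  role <- match.arg(role)
  if (!inherits(voi, "voi_mask")) stop("`voi` must be a `voi_mask`")
  if (!same_grid(scan$grid, voi$grid)) stop("VOI grid does not match scan grid")
  if (!any(voi$mask)) stop("VOI mask is empty")
  nf <- n_frames(scan$framing)
  idx <- which(voi$mask)
  nvox <- prod(scan$grid$dim)
  vals <- vapply(seq_len(nf), function(f) {
    mean(scan$data[(f - 1L) * nvox + idx])
  }, numeric(1))
  new_tac(scan$framing, vals, role = role, volume_mL = voi_volume_mL(voi))
}

new_tac <- function(framing, values, role, volume_mL = NA_real_) {
  out <- tibble::tibble(
    frame = framing$frame,
    mid_time_s = framing$mid_time_s,
    duration_s = framing$duration_s,
    value = values
  )
  class(out) <- c("pet_tac", class(out))
  attr(out, "role") <- role
  attr(out, "volume_mL") <- volume_mL
  out
}

#' Write / read a time-activity curve as CSV
#'
#' Plain-text interchange: columns `frame_index`, `mid_time_s`,
#' `duration_s`, `concentration_kBq_per_mL`, `role`, `volume_mL`.
#'
#' @param tac A `pet_tac` (or compatible tibble).
#' @param path CSV file path.
#' @return `write_tac_csv()` returns `path` invisibly; `read_tac_csv()`
#'   returns a `pet_tac`.
#' @export
write_tac_csv <- function(tac, path) {
  df <- data.frame(
    frame_index = tac$frame,
    mid_time_s = tac$mid_time_s,
    duration_s = tac$duration_s,
    concentration_kBq_per_mL = tac$value,
    role = attr(tac, "role") %||% "tissue",
    volume_mL = attr(tac, "volume_mL") %||% NA_real_
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame_index", "mid_time_s", "duration_s",
            "concentration_kBq_per_mL")
  if (!all(need %in% names(df))) stop("missing TAC columns in CSV")
  out <- tibble::tibble(
    frame = as.integer(df$frame_index),
    mid_time_s = df$mid_time_s,
    duration_s = df$duration_s,
    value = df$concentration_kBq_per_mL
  )
  class(out) <- c("pet_tac", class(out))
  attr(out, "role") <- if ("role" %in% names(df)) as.character(df$role[1]) else "tissue"
  attr(out, "volume_mL") <- if ("volume_mL" %in% names(df)) df$volume_mL[1] else NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground-truth curve of one tissue
#'
#' Pulls the exact noiseless frame curve of one tissue from a simulated
#' scan's ground-truth record, as a `pet_tac`.
#'
#' @param scan A `pet_scan`.
#' @param tissue Tissue name (e.g. `"posterior"`, `"artery"`).
#' @return A `pet_tac`.
#' @export
ground_truth_tac <- function(scan, tissue) {
  cur <- scan$ground_truth$curves
  sel <- cur[cur$tissue == tissue, ]
  if (nrow(sel) == 0L) stop(sprintf("no ground truth for tissue '%s'", tissue))
  new_tac(scan$framing, sel$value,
          role = if (tissue == "artery") "input" else "tissue")
}
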