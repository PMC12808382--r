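#' Dynamic PET framing scheme
#'
#' Expands a grouped frame description, e.g. "8 x 5 s, 3 x 10 s, ...", into
#' the full ordered table of contiguous time frames. The default is the
#' 22-frame clinical lower-leg protocol (8 x 5, 3 x 10, 4 x 15, 6 x 30,
#' 1 x 60 s; 370 s total).
#'
#' @param groups A list of `c(count, duration_s)` pairs, in acquisition
#'   order. Counts must be positive integers, durations positive seconds.
#' @return A tibble of class `pet_framing` with one row per frame and
#'   columns `frame` (1-based index), `start_s`, `duration_s`, `mid_time_s`.
#'   Frames are contiguous and non-overlapping: each frame starts where the
#'   previous one ended, and the first starts at 0.
#' @examples
#' framing_scheme()                      # the 22-frame default
#' framing_scheme(list(c(4, 10), c(2, 30)))
#' @export
framing_scheme <- function(groups = list(c(8, 5), c(3, 10), c(4, 15),
                                         c(6, 30), c(1, 60))) {
  if (!is.list(groups) || length(groups) == 0L) {
    stop("`groups` must be a non-empty list of c(count, duration_s) pairs")
  }
  for (g in groups) {
    if (length(g) != 2L || !is.numeric(g)) {
      stop("each group must be a numeric pair c(count, duration_s)")
    }
    if (g[1] < 1 || g[1] != round(g[1])) {
      stop("frame counts must be positive integers")
    }
    if (g[2] <= 0) stop("frame durations must be positive")
  }
  durations <- unlist(lapply(groups, function(g) rep(g[2], g[1])))
  starts <- cumsum(c(0, durations[-length(durations)]))
  out <- tibble::tibble(
    frame = seq_along(durations),
    start_s = starts,
    duration_s = durations,
    mid_time_s = starts + durations / 2
  )
  class(out) <- c("pet_framing", class(out))
  attr(out, "groups") <- groups
  out
}

#' @export
print.pet_framing <- function(x, ...) {
  cat(sprintf("<pet_framing> %d frames, total %g s\n",
              nrow(x), sum(x$duration_s)))
  NextMethod()
}

n_frames <- function(framing) nrow(framing)

total_duration <- function(framing) sum(framing$duration_s)

stopifnot_framing <- function(framing) {
  if (!inherits(framing, "pet_framing")) stop("expected a `pet_framing` object")
  invisible(framing)
}

#' Radioactive decay specification
#'
#' Physical-decay parameters used both when simulating measured activity and
#' when correcting frame values back to a common reference time. The default
#' half-life is the physical half-life of oxygen-15 (122.24 s); the decay
#' reference time defaults to scan start (t = 0), the usual dynamic-PET
#' convention with injection at acquisition start.
#'
#' @param half_life_s Isotope half-life in seconds.
#' @param reference_time_s Time (s) to which activities are decay-corrected.
#' @return A list of class `decay_spec` with elements `half_life_s`,
#'   `lambda_per_s` (= log(2)/half-life) and `reference_time_s`.
#' @examples
#' decay_spec()           # oxygen-15
#' decay_spec(6586.2)     # fluorine-18
#' @export
decay_spec <- function(half_life_s = 122.24, reference_time_s = 0) {
  if (!is.numeric(half_life_s) || length(half_life_s) != 1L ||
      !is.finite(half_life_s) || half_life_s <= 0) {
    stop("`half_life_s` must be a positive finite number")
  }
  structure(
    list(
      half_life_s = half_life_s,
      lambda_per_s = log(2) / half_life_s,
      reference_time_s = reference_time_s
    ),
    class = "decay_spec"
  )
}

#' Frame decay-correction factor
#'
#' Factor `F` such that (measured frame-average of decaying activity) * `F`
#' equals the frame-average of the decay-corrected activity, under the
#' standard assumption that the underlying decay-corrected activity is
#' constant over the frame:
#' `F = exp(lambda * (t0 - t_ref)) * lambda * dt / (1 - exp(-lambda * dt))`
#' for a frame starting at `t0` with duration `dt`.
#'
#' @param start_s Frame start time(s), seconds. Vectorised.
#' @param duration_s Frame duration(s), seconds, > 0. Vectorised.
#' @param spec A [decay_spec()].
#' @return Positive numeric factor(s), one per frame.
#' @examples
#' decay_correction_factor(40, 10, decay_spec())
#' @export
decay_correction_factor <- function(start_s, duration_s, spec = decay_spec()) {
  if (!inherits(spec, "decay_spec")) stop("`spec` must be a `decay_spec`")
  if (any(duration_s <= 0)) stop("frame durations must be positive")
  lam <- spec$lambda_per_s
  x <- lam * duration_s
  # lam*dt / (1 - exp(-lam*dt)), stable as x -> 0 (-> 1)
  shape <- ifelse(x < 1e-8, 1 + x / 2, x / (1 - exp(-x)))
  exp(lam * (start_s - spec$reference_time_s)) * shape
}

#' Write / read the framing sidecar
#'
#' The framing scheme travels next to the 4D volume as a small JSON sidecar:
#' `{"frame_starts_s": [...], "frame_durations_s": [...],
#'   "decay_corrected": true, "half_life_s": 122.24}`.
#'
#' @param framing A [framing_scheme()].
#' @param path File path for the JSON sidecar.
#' @param decay_corrected Logical flag stored in the sidecar.
#' @param half_life_s Half-life recorded in the sidecar.
#' @return `write_framing_json()` returns `path` invisibly;
#'   `read_framing_json()` returns a list with elements `framing`
#'   (a `pet_framing`), `decay_corrected` and `half_life_s`.
#' @export
write_framing_json <- function(framing, path, decay_corrected = TRUE,
                               half_life_s = 122.24) {
  stopifnot_framing(framing)
  jsonlite::write_json(
    list(
      frame_starts_s = framing$start_s,
      frame_durations_s = framing$duration_s,
      decay_corrected = decay_corrected,
      half_life_s = half_life_s
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_framing_json
#' @export
read_framing_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  starts <- as.numeric(x$frame_starts_s)
  durs <- as.numeric(x$frame_durations_s)
  if (length(starts) != length(durs)) {
    stop("sidecar start/duration lengths disagree")
  }
  if (any(abs(starts - cumsum(c(0, durs[-length(durs)]))) > 1e-9)) {
    stop("sidecar frames are not contiguous from t = 0")
  }
  out <- tibble::tibble(
    frame = seq_along(durs),
    start_s = starts,
    duration_s = durs,
    mid_time_s = starts + durs / 2
  )
  class(out) <- c("pet_framing", class(out))
  list(
    framing = out,
    decay_corrected = isTRUE(x$decay_corrected),
    half_life_s = as.numeric(x$half_life_s)
  )
}
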