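#' Parametric digital lower-leg phantom
#'
#' Geometry of a synthetic lower-leg cross-section used to drive the whole
#' pipeline with known ground truth: a cylindrical leg containing two bone
#' cylinders (tibia, fibula), an arterial cylinder standing in for the
#' superficial femoral artery, and muscle split into a posterior and an
#' anterior compartment by a coronal plane. Anatomical realism is not the
#' point — the analysis consumes label volumes, so parametric cylinders
#' keep every geometric quantity exact and testable.
#'
#' All coordinates are world mm on the [pet_grid()] convention (z axial,
#' increasing foot to abdomen). The landmark coordinates (`malleolus_z_mm`,
#' `knee_z_mm`, `artery_bifurcation_z_mm`) are abstract positions used by
#' the level and IDIF placement rules; they need not lie inside the
#' simulated slab.
#'
#' @param dim Grid dimensions `(nx, ny, nz)`.
#' @param voxel_mm Voxel edge lengths (mm).
#' @param leg_center_mm,leg_radius_mm In-plane centre and radius of the leg.
#' @param tibia_center_mm,tibia_radius_mm In-plane centre and radius of the
#'   tibia cylinder.
#' @param fibula_center_mm,fibula_radius_mm Likewise for the fibula.
#' @param artery_center_mm,artery_radius_mm Likewise for the artery.
#' @param posterior_y_mm Coronal plane (mm): leg voxels with y-centre at or
#'   beyond it form the posterior muscle compartment.
#' @param malleolus_z_mm,knee_z_mm Axial landmarks (distal end of the medial
#'   malleolus, knee joint space) defining the lower-leg length.
#' @param artery_bifurcation_z_mm Axial position of the common femoral
#'   artery bifurcation, reference point for IDIF placement.
#' @return A list of class `leg_phantom`.
#' @examples
#' ph <- leg_phantom()
#' table(phantom_labels(ph))
#' @export
leg_phantom <- function(dim = c(64, 64, 48),
                        voxel_mm = c(1.65, 1.65, 1.5),
                        leg_center_mm = c(52.8, 52.8),
                        leg_radius_mm = 48,
                        tibia_center_mm = c(42, 38),
                        tibia_radius_mm = 7,
                        fibula_center_mm = c(68, 42),
                        fibula_radius_mm = 4,
                        artery_center_mm = c(52.8, 66),
                        artery_radius_mm = 3,
                        posterior_y_mm = 58,
                        malleolus_z_mm = 0,
                        knee_z_mm = 60,
                        artery_bifurcation_z_mm = 66) {
  if (malleolus_z_mm >= knee_z_mm) {
    stop("`malleolus_z_mm` must be below `knee_z_mm`")
  }
  bone_dists <- c(
    sqrt(sum((artery_center_mm - tibia_center_mm)^2)) -
      (artery_radius_mm + tibia_radius_mm),
    sqrt(sum((artery_center_mm - fibula_center_mm)^2)) -
      (artery_radius_mm + fibula_radius_mm)
  )
  if (any(bone_dists <= 0)) stop("artery cylinder intersects bone")
  structure(
    list(grid = pet_grid(dim, voxel_mm),
         leg_center_mm = leg_center_mm, leg_radius_mm = leg_radius_mm,
         tibia_center_mm = tibia_center_mm, tibia_radius_mm = tibia_radius_mm,
         fibula_center_mm = fibula_center_mm,
         fibula_radius_mm = fibula_radius_mm,
         artery_center_mm = artery_center_mm,
         artery_radius_mm = artery_radius_mm,
         posterior_y_mm = posterior_y_mm,
         malleolus_z_mm = malleolus_z_mm, knee_z_mm = knee_z_mm,
         artery_bifurcation_z_mm = artery_bifurcation_z_mm),
    class = "leg_phantom"
  )
}

#' @rdname leg_phantom
#' @format NULL
#' @export
phantom_label_codes <- c(
  background = 0L, tibia = 1L, fibula = 2L,
  posterior = 3L, anterior = 4L, artery = 5L
)

#' @rdname leg_phantom
#' @param phantom A `leg_phantom`.
#' @return `phantom_labels()`: an integer array of grid dimensions with the
#'   codes in `phantom_label_codes`; tissue labels are pairwise disjoint by
#'   construction.
#' @export
phantom_labels <- function(phantom) {
  g <- phantom$grid
  x <- axis_centers_mm(g, 1)
  y <- axis_centers_mm(g, 2)
  xg <- matrix(rep(x, times = g$dim[2]), g$dim[1], g$dim[2])
  yg <- matrix(rep(y, each = g$dim[1]), g$dim[1], g$dim[2])

  in_disc <- function(center, radius) {
    (xg - center[1])^2 + (yg - center[2])^2 <= radius^2
  }
  leg <- in_disc(phantom$leg_center_mm, phantom$leg_radius_mm)
  tibia <- in_disc(phantom$tibia_center_mm, phantom$tibia_radius_mm) & leg
  fibula <- in_disc(phantom$fibula_center_mm, phantom$fibula_radius_mm) & leg
  artery <- in_disc(phantom$artery_center_mm, phantom$artery_radius_mm) & leg
  artery <- artery & !tibia & !fibula
  muscle <- leg & !tibia & !fibula & !artery
  posterior <- muscle & (yg >= phantom$posterior_y_mm)
  anterior <- muscle & !posterior

  slice <- matrix(phantom_label_codes[["background"]], g$dim[1], g$dim[2])
  slice[tibia] <- phantom_label_codes[["tibia"]]
  slice[fibula] <- phantom_label_codes[["fibula"]]
  slice[posterior] <- phantom_label_codes[["posterior"]]
  slice[anterior] <- phantom_label_codes[["anterior"]]
  slice[artery] <- phantom_label_codes[["artery"]]
  array(rep(slice, g$dim[3]), dim = g$dim)
}

#' Ground-truth tissue kinetics for the phantom
#'
#' One row per muscle compartment: influx `k1` (mL/100 cm^3/min), efflux
#' `k2` (1/min) and the blood delay (s) between the arterial sampling site
#' and the tissue. Defaults sit mid-range of perfusion values observed in
#' calf muscle of peripheral-arterial-disease patients
#' (about 1.5-5.2 mL/100 cm^3/min).
#'
#' @param posterior,anterior Numeric vectors `c(k1, k2, delay_s)`.
#' @return A tibble of class `tissue_kinetics` with columns `tissue`, `k1`,
#'   `k2`, `delay_s`.
#' @examples
#' tissue_kinetics(posterior = c(4.5, 0.4, 4))
#' @export
tissue_kinetics <- function(posterior = c(3.0, 0.3, 5),
                            anterior = c(2.0, 0.25, 6)) {
  rows <- list(posterior = posterior, anterior = anterior)
  for (r in rows) {
    if (length(r) != 3L) stop("each tissue needs c(k1, k2, delay_s)")
    if (r[1] < 0) stop("k1 must be non-negative")
    if (r[2] <= 0) stop("k2 must be positive")
    if (r[3] < 0) stop("delay must be non-negative")
  }
  out <- tibble::tibble(
    tissue = names(rows),
    k1 = unname(vapply(rows, `[`, numeric(1), 1)),
    k2 = unname(vapply(rows, `[`, numeric(1), 2)),
    delay_s = unname(vapply(rows, `[`, numeric(1), 3))
  )
  class(out) <- c("tissue_kinetics", class(out))
  out
}

#' Efflux rate from the blood-tissue partition coefficient
#'
#' For a freely diffusible tracer the efflux rate is tied to influx by the
#' partition coefficient `p`: `k2 = (k1 / 100) / p` per minute, with `k1`
#' in mL/100 cm^3/min and `p` in mL/cm^3. A helper for users who prefer the
#' physiological coupling over free `(k1, k2)` choices.
#'
#' @param k1 Influx rate, mL/100 cm^3/min.
#' @param partition_mL_cm3 Partition coefficient (mL/cm^3).
#' @return Efflux rate in 1/min.
#' @export
k2_from_partition <- function(k1, partition_mL_cm3 = 0.9) {
  if (partition_mL_cm3 <= 0) stop("partition coefficient must be positive")
  (k1 / 100) / partition_mL_cm3
}

#' Poisson count-noise model
#'
#' Pseudo-count noise: a voxel holding (decayed) concentration `C` kBq/mL in
#' a frame of duration `dt` s contributes an expected
#' `kappa * C * dt * V` counts (`V` the voxel volume in mL); the simulator
#' draws Poisson counts and converts back to concentration, so noise
#' variance scales inversely with frame duration, as in reconstructed PET.
#' `kappa = 0` switches noise off exactly.
#'
#' @param kappa Count-scale factor (counts per kBq/mL per s per mL), >= 0.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(kappa = 0) {
  if (kappa < 0) stop("`kappa` must be non-negative")
  structure(list(kappa = kappa), class = "noise_model")
}

#' Count scale achieving a target TAC coefficient of variation
#'
#' Inverts the Poisson noise model: the mean TAC over `n_vox` voxels at
#' concentration `conc` in a frame of duration `duration_s` has
#' `CV = 1 / sqrt(n_vox * kappa * conc * dt * V)`; this returns the `kappa`
#' giving the requested CV at that operating point.
#'
#' @param cv Target coefficient of variation (e.g. 0.05).
#' @param conc Reference concentration (kBq/mL).
#' @param duration_s Reference frame duration (s).
#' @param n_vox Number of voxels averaged in the TAC.
#' @param grid A [pet_grid()] supplying the voxel volume.
#' @return The count-scale factor `kappa`.
#' @export
kappa_for_cv <- function(cv, conc, duration_s, n_vox, grid = pet_grid(c(64, 64, 48))) {
  if (cv <= 0) stop("`cv` must be positive")
  1 / (cv^2 * n_vox * conc * duration_s * voxel_volume_mL(grid))
}

# Evaluate expr with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a dynamic lower-leg PET acquisition
#'
#' Builds a 4D dynamic volume on the phantom grid: artery voxels carry the
#' (frame-averaged) arterial input curve, each muscle compartment carries
#' its forward one-tissue-compartment curve, bone and background are cold.
#' Physical decay is applied on the fine time grid before frame averaging;
#' Poisson pseudo-count noise (see [noise_model()]) perturbs the decayed
#' frame values; decay correction (the standard reconstruction step) then
#' rescales frames back to the reference time when `decay_correct = TRUE`.
#' The returned ground truth holds the exact noiseless per-tissue frame
#' curves produced by the identical processing chain, plus the generating
#' parameters.
#'
#' @param phantom A [leg_phantom()].
#' @param aif An [aif_model()].
#' @param kinetics A [tissue_kinetics()] table; its tissues must exist in
#'   the phantom label volume.
#' @param framing A [framing_scheme()].
#' @param decay A [decay_spec()], or `NULL` to simulate without radioactive
#'   decay.
#' @param noise A [noise_model()].
#' @param seed Integer seed for the noise draws; the caller's RNG state is
#'   preserved. Identical seeds give bit-identical output.
#' @param decay_correct Apply frame decay correction to the output (only
#'   meaningful when `decay` is given).
#' @param fine_step_s Fine integration step (s) for the forward curves.
#' @return A list of class `pet_scan`: `data` (4D array x,y,z,frame, kBq/mL),
#'   `grid`, `framing`, `labels`, `decay`, `decay_corrected`,
#'   `ground_truth` (list of `curves` tibble and `params`), `phantom`,
#'   `seed`.
#' @examples
#' scan <- simulate_dynamic_scan(noise = noise_model(0))
#' dim(scan$data)
#' @export
simulate_dynamic_scan <- function(phantom = leg_phantom(),
                                  aif = aif_model(),
                                  kinetics = tissue_kinetics(),
                                  framing = framing_scheme(),
                                  decay = decay_spec(),
                                  noise = noise_model(),
                                  seed = NULL,
                                  decay_correct = TRUE,
                                  fine_step_s = 0.05) {
  stopifnot_framing(framing)
  if (!inherits(noise, "noise_model")) stop("`noise` must be a `noise_model`")
  labels <- phantom_labels(phantom)
  present <- unique(as.integer(labels))
  for (tis in kinetics$tissue) {
    code <- phantom_label_codes[tis]
    if (is.na(code) || !(code %in% present)) {
      stop(sprintf("kinetics tissue '%s' not present in the phantom", tis))
    }
  }

  t_end <- total_duration(framing)
  tf <- seq(0, t_end, by = fine_step_s)
  aif_fun <- function(t) aif_value(aif, t)

  # fine-grid true (decay-corrected convention) curves per label code
  fine_curves <- list()
  fine_curves[[as.character(phantom_label_codes[["artery"]])]] <- aif_fun(tf)
  for (i in seq_len(nrow(kinetics))) {
    code <- phantom_label_codes[[kinetics$tissue[i]]]
    fine_curves[[as.character(code)]] <- forward_1tcm_fine(
      kinetics$k1[i], kinetics$k2[i], kinetics$delay_s[i],
      aif_fun, tf, fine_step_s
    )
  }

  decay_fine <- if (is.null(decay)) rep(1, length(tf)) else {
    exp(-decay$lambda_per_s * (tf - decay$reference_time_s))
  }
  corr <- if (!is.null(decay) && decay_correct) {
    decay_correction_factor(framing$start_s, framing$duration_s, decay)
  } else {
    rep(1, nrow(framing))
  }

  # measured (decayed) and output (optionally corrected) frame values
  measured <- lapply(fine_curves, function(cv) {
    frame_average(tf, cv * decay_fine, framing)
  })
  truth_frames <- lapply(measured, function(m) m * corr)

  nf <- nrow(framing)
  data <- array(0, dim = c(phantom$grid$dim, nf))
  vox_ml <- voxel_volume_mL(phantom$grid)
  idx_by_code <- lapply(names(fine_curves), function(cd) {
    which(labels == as.integer(cd))
  })
  names(idx_by_code) <- names(fine_curves)

  with_local_seed(seed, {
    for (f in seq_len(nf)) {
      vol <- array(0, dim = phantom$grid$dim)
      for (cd in names(fine_curves)) {
        idx <- idx_by_code[[cd]]
        mval <- measured[[cd]][f]
        if (noise$kappa > 0 && mval > 0) {
          lam <- noise$kappa * mval * framing$duration_s[f] * vox_ml
          vol[idx] <- stats::rpois(length(idx), lam) /
            (noise$kappa * framing$duration_s[f] * vox_ml)
        } else {
          vol[idx] <- mval
        }
      }
      data[, , , f] <- vol * corr[f]
    }
  })

  truth_tbl <- dplyr::bind_rows(lapply(names(truth_frames), function(cd) {
    code <- as.integer(cd)
    tibble::tibble(
      tissue = names(phantom_label_codes)[match(code, phantom_label_codes)],
      frame = framing$frame,
      mid_time_s = framing$mid_time_s,
      duration_s = framing$duration_s,
      value = truth_frames[[cd]]
    )
  }))

  structure(
    list(data = data, grid = phantom$grid, framing = framing,
         labels = labels, decay = decay,
         decay_corrected = !is.null(decay) && decay_correct,
         ground_truth = list(curves = truth_tbl,
                             params = list(aif = aif, kinetics = kinetics,
                                           noise = noise)),
         phantom = phantom, seed = seed),
    class = "pet_scan"
  )
}

#' @export
print.pet_scan <- function(x, ...) {
  cat(sprintf(
    "<pet_scan> %d x %d x %d voxels, %d frames (%g s)%s\n",
    x$grid$dim[1], x$grid$dim[2], x$grid$dim[3],
    n_frames(x$framing), total_duration(x$framing),
    if (x$decay_corrected) ", decay-corrected" else ""
  ))
  invisible(x)
}

#' Simulated noisy replicate of a time-activity curve
#'
#' Draws the Poisson noise a region-mean TAC over `n_vox` voxels would show
#' under [noise_model()], without materialising the full 4D volume: the
#' mean of `n` i.i.d. Poisson voxels equals a single Poisson draw at `n`
#' times the expected counts, rescaled. Used for replicate studies of fit
#' precision.
#'
#' @param tac A tibble with columns `duration_s` and `value` (a noiseless
#'   frame-averaged curve).
#' @param n_vox Number of voxels averaged by the VOI.
#' @param noise A [noise_model()] with `kappa > 0`.
#' @param grid A [pet_grid()] supplying the voxel volume.
#' @return The input tibble with `value` replaced by one noisy replicate.
#' @export
simulate_noisy_tac <- function(tac, n_vox, noise, grid = pet_grid(c(64, 64, 48))) {
  if (!inherits(noise, "noise_model") || noise$kappa <= 0) {
    stop("`noise` must be a `noise_model` with kappa > 0")
  }
  scale <- noise$kappa * tac$duration_s * voxel_volume_mL(grid) * n_vox
  lam <- pmax(tac$value, 0) * scale
  out <- tac
  out$value <- stats::rpois(length(lam), lam) / scale
  out
}
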