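#' Intraclass correlation ICC(2,1)
#'
#' Absolute-agreement intraclass correlation under a two-way random-effects
#' model for single measures: subjects (legs) in rows, measurements
#' (rater-sessions) in columns. From the two-way ANOVA mean squares
#' (MSR between subjects, MSC between measurements, MSE residual),
#'
#' \deqn{ICC(2,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)},}
#'
#' with the 95% confidence interval by the McGraw-Wong F-distribution
#' method (Satterthwaite degrees of freedom for the lower-bound
#' denominator). Absolute agreement penalises systematic offsets between
#' measurements, unlike the consistency form.
#'
#' @param ratings Numeric `n x k` matrix (subjects x measurements), or a
#'   data frame with columns `subject`, `measurement`, `value` forming a
#'   complete design.
#' @param conf_level Confidence level for the interval.
#' @param type `"agreement"` for ICC(2,1) (default); `"consistency"` for
#'   the ICC(3,1) variant, provided as a labelled extra only.
#' @return A tibble of class `pet_icc`: `icc`, `lower`, `upper`,
#'   `interpretation`, `msr`, `msc`, `mse`, `n`, `k`, `type`, `status`
#'   (`"ok"`, or `"undefined"` for a constant matrix, where `icc` is `NA`
#'   rather than an error).
#' @examples
#' m <- cbind(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 4.2))
#' icc_2_1(m)
#' @export
icc_2_1 <- function(ratings, conf_level = 0.95,
                    type = c("agreement", "consistency")) {
  type <- match.arg(type)
  m <- as_ratings_matrix(ratings)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 measurements")
  if (anyNA(m)) stop("ratings must form a complete design (no missing cells)")

  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  if (sst < .Machine$double.eps * max(1, abs(grand))^2 * n * k) {
    return(new_pet_icc(NA_real_, NA_real_, NA_real_, msr, msc, mse, n, k,
                       type, "undefined"))
  }

  if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    fl <- (msr / mse) / stats::qf(1 - (1 - conf_level) / 2,
                                  n - 1, (n - 1) * (k - 1))
    fu <- (msr / mse) * stats::qf(1 - (1 - conf_level) / 2,
                                  (n - 1) * (k - 1), n - 1)
    lower <- (fl - 1) / (fl + k - 1)
    upper <- (fu - 1) / (fu + k - 1)
    return(new_pet_icc(icc, lower, upper, msr, msc, mse, n, k, type, "ok"))
  }

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  if (abs(1 - icc) < 1e-12) {
    lower <- icc
    upper <- 1
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  }
  new_pet_icc(icc, min(lower, icc), max(upper, icc), msr, msc, mse, n, k,
              type, "ok")
}

new_pet_icc <- function(icc, lower, upper, msr, msc, mse, n, k, type,
                        status) {
  out <- tibble::tibble(
    icc = icc, lower = lower, upper = upper,
    interpretation = if (is.na(icc)) NA_character_ else interpret_icc(icc),
    msr = msr, msc = msc, mse = mse, n = n, k = k, type = type,
    status = status
  )
  class(out) <- c("pet_icc", class(out))
  out
}

as_ratings_matrix <- function(ratings) {
  if (is.matrix(ratings)) return(ratings)
  df <- as.data.frame(ratings)
  need <- c("subject", "measurement", "value")
  if (!all(need %in% names(df))) {
    stop("data-frame ratings need columns subject, measurement, value")
  }
  wide <- tapply(df$value, list(df$subject, df$measurement), function(v) {
    if (length(v) != 1L) stop("duplicate cells in ratings") else v
  })
  matrix(wide, nrow = nrow(wide), dimnames = dimnames(wide))
}

#' Qualitative reliability band of an ICC value
#'
#' Conventional interpretation bands: below 0.5 poor, 0.5 to below 0.75
#' moderate, 0.75 through 0.9 good, above 0.9 excellent. The published
#' bands overlap at their endpoints; the half-open convention used here
#' (`[0.5, 0.75)` moderate, `[0.75, 0.9]` good, `(0.9, 1]` excellent) is
#' part of the returned contract.
#'
#' @param icc ICC value(s) in (-1, 1].
#' @return Character vector of labels.
#' @examples
#' interpret_icc(c(0.4, 0.6, 0.89, 0.95))
#' @export
interpret_icc <- function(icc) {
  if (any(is.na(icc)) || any(icc <= -1) || any(icc > 1)) {
    stop("ICC values must lie in (-1, 1]")
  }
  out <- character(length(icc))
  out[icc < 0.5] <- "poor"
  out[icc >= 0.5 & icc < 0.75] <- "moderate"
  out[icc >= 0.75 & icc <= 0.9] <- "good"
  out[icc > 0.9] <- "excellent"
  out
}

#' Bland-Altman limits of agreement
#'
#' Differences `d = x - y`: bias is their mean, and the limits of agreement
#' are bias +/- 1.96 times the sample standard deviation of the
#' differences (1.96 used literally, not a t-quantile).
#'
#' @param x,y Paired measurement vectors of equal length >= 2.
#' @return A one-row tibble of class `pet_ba`: `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `n`, plus `bias_lower`/`bias_upper`, a 95%
#'   t-interval for the bias (zero inside it means no detectable
#'   systematic difference).
#' @examples
#' bland_altman(c(1, 2, 3), c(2, 2, 2))
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  half <- stats::qt(0.975, length(d) - 1) * sd_diff / sqrt(length(d))
  out <- tibble::tibble(
    bias = bias, sd_diff = sd_diff,
    loa_lower = bias - 1.96 * sd_diff,
    loa_upper = bias + 1.96 * sd_diff,
    bias_lower = bias - half, bias_upper = bias + half,
    n = length(d)
  )
  class(out) <- c("pet_ba", class(out))
  out
}

#' Mean with a t-distribution confidence interval
#'
#' @param values Numeric vector, length >= 2.
#' @param level Confidence level.
#' @return A one-row tibble: `mean`, `lower`, `upper`, `n`.
#' @examples
#' mean_with_ci(c(1, 2, 3))
#' @export
mean_with_ci <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  m <- mean(values)
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(values) / sqrt(n)
  tibble::tibble(mean = m, lower = m - half, upper = m + half, n = n)
}

#' In-silico intra-/interrater reproducibility study
#'
#' Emulates the manual reading study on simulated data: several phantom
#' legs with perfusion spanning the observed clinical range are scanned
#' once each (the scan, including its noise realisation, is what both
#' raters analyse, exactly as in a reading study); each virtual
#' rater-session then re-places the VOIs under independent small
#' perturbations — spherical-VOI centres jittered in-plane, the contour
#' VOI dilated or eroded by up to one voxel step, the IDIF start plane
#' shifted by up to one plane — and the whole TAC-extraction plus kinetic
#' fit is rerun. K1 ratings are assembled per VOI method and summarised as
#' intrarater ICCs (per rater, session 1 vs 2) and interrater ICCs (all
#' four rater-session pairings, labelled), each with Bland-Altman limits.
#'
#' @param n_legs Number of simulated legs (>= 2).
#' @param k1_range Ground-truth posterior K1 range (mL/100 cm^3/min)
#'   spanned evenly by the legs.
#' @param k2_range Ground-truth k2 range (1/min) spanned alongside.
#' @param n_raters,n_sessions Virtual raters and sessions per rater.
#' @param sphere_sigma_mm SD of the sphere-centre jitter (mm).
#' @param contour_steps Maximum morphological jitter of the contour VOI in
#'   single-voxel steps (draws from `-contour_steps:contour_steps`).
#' @param idif_plane_jitter Maximum IDIF start-plane shift in planes.
#' @param noise A [noise_model()] for the simulated scans. The default
#'   count scale puts the late-frame coefficient of variation of the
#'   contour-VOI TAC near 5% on the default phantom, the same operating
#'   point used for replicate precision studies.
#' @param seed Integer seed; fixed seed gives an identical study.
#' @param phantom,framing,decay Shared simulation settings.
#' @param fit_cfg A [fit_config()].
#' @return A list of class `pet_rater_study`: `ratings` (tibble: leg,
#'   rater, session, method, k1, true_k1), `agreement` (tibble: method,
#'   design, comparison, icc, lower, upper, interpretation, bias,
#'   loa_lower, loa_upper), `seed`.
#' @export
virtual_rater_study <- function(n_legs = 10,
                                k1_range = c(1.5, 5.2),
                                k2_range = c(0.2, 0.6),
                                n_raters = 2, n_sessions = 2,
                                sphere_sigma_mm = 1,
                                contour_steps = 1,
                                idif_plane_jitter = 1,
                                noise = noise_model(0.4),
                                seed = NULL,
                                phantom = leg_phantom(),
                                framing = framing_scheme(),
                                decay = decay_spec(),
                                fit_cfg = fit_config()) {
  if (n_legs < 2L) stop("need at least 2 simulated legs")
  k1_true <- seq(k1_range[1], k1_range[2], length.out = n_legs)
  k2_true <- seq(k2_range[1], k2_range[2], length.out = n_legs)

  ratings <- with_local_seed(seed, {
    leg_seeds <- sample.int(.Machine$integer.max - 1L, n_legs)
    cell_seeds <- array(
      sample.int(.Machine$integer.max - 1L, n_legs * n_raters * n_sessions),
      dim = c(n_legs, n_raters, n_sessions)
    )
    rows <- list()
    for (leg in seq_len(n_legs)) {
      scan <- simulate_dynamic_scan(
        phantom = phantom, aif = aif_model(),
        kinetics = tissue_kinetics(
          posterior = c(k1_true[leg], k2_true[leg], 5)
        ),
        framing = framing, decay = decay, noise = noise,
        seed = leg_seeds[leg]
      )
      base <- analysis_inputs(scan)
      for (r in seq_len(n_raters)) {
        for (s in seq_len(n_sessions)) {
          k1s <- with_local_seed(cell_seeds[leg, r, s], {
            rate_leg(scan, base, sphere_sigma_mm, contour_steps,
                     idif_plane_jitter, fit_cfg)
          })
          rows[[length(rows) + 1L]] <- tibble::tibble(
            leg = leg, rater = r, session = s,
            method = c("contour", "spheres"),
            k1 = c(k1s[["contour"]], k1s[["spheres"]]),
            true_k1 = k1_true[leg]
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })

  agreement <- summarise_rater_study(ratings, n_raters, n_sessions)
  structure(list(ratings = ratings, agreement = agreement, seed = seed),
            class = "pet_rater_study")
}

# shared per-leg geometry that does not depend on the rater
analysis_inputs <- function(scan) {
  ph <- scan$phantom
  g <- scan$grid
  level <- lower_leg_level(ph$malleolus_z_mm, ph$knee_z_mm)
  bone <- voi_mask(
    scan$labels == phantom_label_codes[["tibia"]] |
      scan$labels == phantom_label_codes[["fibula"]],
    g
  )
  list(
    level_z_mm = level,
    zone = bone_exclusion_zone(bone),
    artery = label_voi(scan$labels, g, "artery"),
    start_plane = locate_start_plane(ph$artery_bifurcation_z_mm, g),
    spheres = default_sphere_centers(scan$labels, g, level)
  )
}

# one rater-session analysis of one leg; RNG already seeded by caller
rate_leg <- function(scan, base, sphere_sigma_mm, contour_steps,
                     idif_plane_jitter, fit_cfg) {
  g <- scan$grid
  plane <- base$start_plane
  if (idif_plane_jitter > 0) {
    plane <- plane + sample(seq(-idif_plane_jitter, idif_plane_jitter), 1)
    plane <- max(1L, min(g$dim[3] - 10L + 1L, plane))
  }
  idif <- extract_idif(scan, base$artery, plane)

  contour <- muscle_contour_voi(scan$labels, g, base$level_z_mm,
                                bone_zone = base$zone)
  if (contour_steps > 0) {
    contour <- morph_jitter(
      contour, sample(seq(-contour_steps, contour_steps), 1)
    )
    # jitter may leak outside the compartment; analysis still uses the
    # muscle label as the underlying support
  }
  spheres <- lapply(base$spheres, function(sp) {
    jit <- if (sphere_sigma_mm > 0) stats::rnorm(2, 0, sphere_sigma_mm) else c(0, 0)
    sphere_spec(sp$center_mm + c(jit, 0), sp$radius_mm)
  })
  sph_voi <- sphere_voi(spheres, g)

  fit_c <- fit_1tcm(extract_tac(scan, contour), idif$tac, fit_cfg)
  fit_s <- fit_1tcm(extract_tac(scan, sph_voi), idif$tac, fit_cfg)
  c(contour = fit_c$k1, spheres = fit_s$k1)
}

summarise_rater_study <- function(ratings, n_raters, n_sessions) {
  out <- list()
  for (method in unique(ratings$method)) {
    rm_ <- ratings[ratings$method == method, ]
    wide <- function(r, s) {
      v <- rm_[rm_$rater == r & rm_$session == s, ]
      v$k1[order(v$leg)]
    }
    # intrarater: per rater, session 1 vs session 2 (vs ...)
    for (r in seq_len(n_raters)) {
      m <- vapply(seq_len(n_sessions), function(s) wide(r, s),
                  numeric(length(unique(rm_$leg))))
      ic <- icc_2_1(m)
      ba <- bland_altman(m[, 1], m[, 2])
      out[[length(out) + 1L]] <- tibble::tibble(
        method = method, design = "intrarater",
        comparison = sprintf("rater %d: session 1 vs 2", r),
        icc = ic$icc, lower = ic$lower, upper = ic$upper,
        interpretation = ic$interpretation,
        bias = ba$bias, loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
        bias_lower = ba$bias_lower, bias_upper = ba$bias_upper
      )
    }
    # interrater: every session pairing across the first two raters
    if (n_raters >= 2) {
      for (s1 in seq_len(n_sessions)) {
        for (s2 in seq_len(n_sessions)) {
          a <- wide(1, s1)
          b <- wide(2, s2)
          ic <- icc_2_1(cbind(a, b))
          ba <- bland_altman(a, b)
          out[[length(out) + 1L]] <- tibble::tibble(
            method = method, design = "interrater",
            comparison = sprintf("rater 1 s%d vs rater 2 s%d", s1, s2),
            icc = ic$icc, lower = ic$lower, upper = ic$upper,
            interpretation = ic$interpretation,
            bias = ba$bias, loa_lower = ba$loa_lower,
            loa_upper = ba$loa_upper,
            bias_lower = ba$bias_lower, bias_upper = ba$bias_upper
          )
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.pet_rater_study <- function(x, ...) {
  cat(sprintf("<pet_rater_study> %d legs, %d ratings\n",
              length(unique(x$ratings$leg)), nrow(x$ratings)))
  print(x$agreement[, c("method", "design", "comparison", "icc",
                        "interpretation", "bias")])
  invisible(x)
}

#' @rdname virtual_rater_study
#' @param x A `pet_rater_study`.
#' @param ... Unused.
#' @return `tidy()`: the agreement summary tibble.
#' @method tidy pet_rater_study
#' @export
tidy.pet_rater_study <- function(x, ...) x$agreement
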