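#' Configuration of the one-tissue-compartment fit
#'
#' The fit searches a delay grid and, per delay, a logarithmic k2 basis
#' grid; given (delay, k2), the optimal K1 >= 0 has a closed form
#' (weighted linear least squares clipped at 0), making the search convex
#' in K1 and fully deterministic. Frame weights proportional to frame
#' duration approximate the statistical precision of longer frames;
#' uniform weights are available for sensitivity analysis.
#'
#' @param delay_min_s,delay_max_s,delay_step_s Blood-delay search grid (s).
#' @param k2_min,k2_max k2 basis-grid range (1/min).
#' @param n_k2 Number of log-spaced k2 basis functions.
#' @param weighting `"duration"` (default) or `"uniform"`.
#' @param fine_step_s Fine convolution step (s).
#' @param polish Refine k2 continuously (golden-section via
#'   [stats::optimize()]) around the best grid point.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(delay_min_s = 0, delay_max_s = 15, delay_step_s = 0.5,
                       k2_min = 0.03, k2_max = 2, n_k2 = 40,
                       weighting = c("duration", "uniform"),
                       fine_step_s = 0.05, polish = TRUE) {
  weighting <- match.arg(weighting)
  if (delay_step_s <= 0) stop("`delay_step_s` must be positive")
  if (delay_max_s < delay_min_s) stop("empty delay grid")
  if (k2_min <= 0 || k2_max <= k2_min) stop("invalid k2 range")
  if (n_k2 < 1) stop("`n_k2` must be at least 1")
  if (fine_step_s <= 0) stop("`fine_step_s` must be positive")
  structure(
    list(delay_grid_s = seq(delay_min_s, delay_max_s, by = delay_step_s),
         k2_grid = exp(seq(log(k2_min), log(k2_max), length.out = n_k2)),
         weighting = weighting, fine_step_s = fine_step_s, polish = polish),
    class = "fit_config"
  )
}

#' Fit the one-tissue compartment model to a tissue curve
#'
#' Estimates perfusion from a (tissue TAC, input function) pair under the
#' model `C_T(t) = K1 * C_a(t - delay) (x) exp(-k2 t)` with no explicit
#' blood-volume term (appropriate for a freely diffusible tracer with high
#' extraction in muscle). The basis-function method is used: for every
#' candidate delay on the grid the input is shifted on the fine grid,
#' convolved with each k2 basis exponential and frame-averaged; the
#' weighted least-squares K1 >= 0 is closed-form per basis, and the
#' (delay, k2, K1) triple with minimal weighted residual sum of squares
#' wins, with optional continuous polish of k2. The fitted model curve is
#' frame-averaged exactly like the data.
#'
#' @param tissue A `pet_tac` (role tissue).
#' @param input A `pet_tac` (role input); must share the tissue framing and
#'   have a positive peak.
#' @param config A [fit_config()].
#' @return A list of class `pet_fit`: `k1` (mL/100 cm^3/min), `k2` (1/min),
#'   `delay_s`, `wrss`, `fitted` (tibble: frame, mid_time_s, observed,
#'   fitted, weight), `converged`, `config`.
#' @examples
#' scan <- simulate_dynamic_scan(noise = noise_model(0))
#' idif <- ground_truth_tac(scan, "artery")
#' tis <- ground_truth_tac(scan, "posterior")
#' fit <- fit_1tcm(tis, idif)
#' tidy(fit)
#' @export
fit_1tcm <- function(tissue, input, config = fit_config()) {
  if (!inherits(config, "fit_config")) stop("`config` must be a `fit_config`")
  if (nrow(tissue) != nrow(input) ||
      any(abs(tissue$mid_time_s - input$mid_time_s) > 1e-9)) {
    stop("tissue and input curves do not share a framing")
  }
  if (max(input$value) <= 0) stop("degenerate input: input function is all zero")

  framing <- tibble::tibble(
    frame = tissue$frame, start_s = tissue$mid_time_s - tissue$duration_s / 2,
    duration_s = tissue$duration_s, mid_time_s = tissue$mid_time_s
  )
  class(framing) <- c("pet_framing", class(framing))

  w <- switch(config$weighting,
    duration = tissue$duration_s / sum(tissue$duration_s),
    uniform = rep(1 / nrow(tissue), nrow(tissue))
  )
  obs <- tissue$value
  h <- config$fine_step_s
  t_end <- max(framing$start_s + framing$duration_s)
  tf <- seq(0, t_end, by = h)

  # all-zero tissue curve: K1 = 0 fits perfectly
  if (all(obs == 0)) {
    fitted <- tibble::tibble(frame = tissue$frame,
                             mid_time_s = tissue$mid_time_s,
                             observed = obs, fitted = 0, weight = w)
    return(new_pet_fit(0, config$k2_grid[1], 0, 0, fitted, TRUE, config))
  }

  # precomputed frame-average operator on the uniform fine grid
  favg <- make_frame_averager(tf, framing, h)

  best <- list(wrss = Inf)
  for (delay in config$delay_grid_s) {
    ca <- eval_input(input, tf - delay)
    for (k2 in config$k2_grid) {
      res <- k1_closed_form(ca, k2, h, favg, obs, w)
      if (res$wrss < best$wrss) {
        best <- c(res, list(delay = delay, k2 = k2, ca = list(ca)))
      }
    }
  }

  if (config$polish && length(config$k2_grid) > 2) {
    ki <- which.min(abs(config$k2_grid - best$k2))
    lo <- config$k2_grid[max(1L, ki - 1L)]
    hi <- config$k2_grid[min(length(config$k2_grid), ki + 1L)]
    if (hi > lo) {
      ca <- best$ca[[1]]
      opt <- stats::optimize(function(k2) {
        k1_closed_form(ca, k2, h, favg, obs, w)$wrss
      }, interval = c(lo, hi))
      if (opt$objective < best$wrss) {
        res <- k1_closed_form(ca, opt$minimum, h, favg, obs, w)
        best <- c(res, list(delay = best$delay, k2 = opt$minimum,
                            ca = list(ca)))
      }
    }
  }

  model <- best$k1_per_s *
    favg(conv_exp_uniform(best$ca[[1]], best$k2 / 60, h))
  fitted <- tibble::tibble(frame = tissue$frame,
                           mid_time_s = tissue$mid_time_s,
                           observed = obs, fitted = model, weight = w)
  new_pet_fit(convert_k1_units(best$k1_per_s * 60), best$k2, best$delay,
              best$wrss, fitted, TRUE, config)
}

# Fast frame averaging via a cumulative trapezoidal integral; frame edges
# are snapped to the nearest fine-grid point (exact when frame starts are
# multiples of the fine step, as with the default framing).
make_frame_averager <- function(tf, framing, h) {
  lo <- pmin(pmax(round(framing$start_s / h), 0) + 1L, length(tf))
  hi <- pmin(round((framing$start_s + framing$duration_s) / h) + 1L,
             length(tf))
  span <- tf[hi] - tf[lo]
  function(y) {
    ct <- c(0, cumsum((y[-length(y)] + y[-1]) * h / 2))
    (ct[hi] - ct[lo]) / span
  }
}

# Closed-form weighted LS coefficient K1 (clipped at 0) for one (delay, k2)
# basis; rates per second internally.
k1_closed_form <- function(ca, k2, h, favg, obs, w) {
  basis <- favg(conv_exp_uniform(ca, k2 / 60, h))
  denom <- sum(w * basis^2)
  k1_per_s <- if (denom > 0) max(0, sum(w * basis * obs) / denom) else 0
  resid <- obs - k1_per_s * basis
  list(k1_per_s = k1_per_s, wrss = sum(w * resid^2))
}

new_pet_fit <- function(k1, k2, delay_s, wrss, fitted, converged, config) {
  structure(
    list(k1 = k1, k2 = k2, delay_s = delay_s, wrss = wrss,
         fitted = fitted, converged = converged, config = config),
    class = "pet_fit"
  )
}

#' @export
print.pet_fit <- function(x, ...) {
  cat(sprintf(
    "<pet_fit> K1 = %.3f mL/100cm^3/min, k2 = %.3f /min, delay = %.1f s, WRSS = %.4g\n",
    x$k1, x$k2, x$delay_s, x$wrss
  ))
  invisible(x)
}

#' Convert K1 to the reporting unit
#'
#' Perfusion is modelled in mL/cm^3/min but reported in mL/100 cm^3/min.
#'
#' @param k1_mL_per_cm3_min K1 in mL/cm^3/min, >= 0.
#' @return `100 * k1_mL_per_cm3_min`.
#' @examples
#' convert_k1_units(0.0375)   # 3.75
#' @export
convert_k1_units <- function(k1_mL_per_cm3_min) {
  if (any(k1_mL_per_cm3_min < 0)) stop("K1 must be non-negative")
  100 * k1_mL_per_cm3_min
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kinetic fit
#'
#' @param x A `pet_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `unit`.
#' @method tidy pet_fit
#' @export
tidy.pet_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k1", "k2", "delay"),
    estimate = c(x$k1, x$k2, x$delay_s),
    unit = c("mL/100cm^3/min", "1/min", "s")
  )
}

#' @rdname tidy.pet_fit
#' @return `glance()`: one-row fit summary (`k1`, `k2`, `delay_s`, `wrss`,
#'   `n_frames`, `converged`).
#' @method glance pet_fit
#' @export
glance.pet_fit <- function(x, ...) {
  tibble::tibble(
    k1 = x$k1, k2 = x$k2, delay_s = x$delay_s, wrss = x$wrss,
    n_frames = nrow(x$fitted), converged = x$converged
  )
}
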