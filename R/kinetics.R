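#' Convolve a sampled curve with a decaying exponential
#'
#' Numerical core of the one-tissue compartment model: computes
#' `y(t) = integral_0^t c(s) exp(-k (t - s)) ds` for a curve `c` given by
#' samples on an arbitrary increasing time grid. The input is interpolated
#' piecewise-linearly onto a uniform fine grid and each linear segment is
#' convolved analytically with the exponential (exact recursion, no
#' quadrature error beyond the linear interpolation), so halving
#' `fine_step_s` changes the result only through the interpolation of `c`.
#'
#' @param t_s Sample times of the input curve (s), increasing.
#' @param values Input curve samples at `t_s`.
#' @param k_per_s Exponential rate constant (1/s), >= 0. `k = 0` gives the
#'   running time-integral of the input.
#' @param fine_step_s Fine-grid step (s), > 0.
#' @param t_end_s End of the output grid; defaults to `max(t_s)`.
#' @return A tibble with columns `t_s` (the uniform fine grid from 0) and
#'   `value` (the convolution).
#' @examples
#' tt <- seq(0, 60, by = 1)
#' convolve_exp(tt, as.numeric(tt > 10), k_per_s = 0.05)
#' @export
convolve_exp <- function(t_s, values, k_per_s, fine_step_s = 0.05,
                         t_end_s = max(t_s)) {
  if (fine_step_s <= 0) stop("`fine_step_s` must be positive")
  if (k_per_s < 0) stop("`k_per_s` must be non-negative")
  if (length(t_s) != length(values)) stop("time/value lengths disagree")
  tf <- seq(0, t_end_s, by = fine_step_s)
  cf <- stats::approx(t_s, values, xout = tf, rule = 2)$y
  tibble::tibble(t_s = tf, value = conv_exp_uniform(cf, k_per_s, fine_step_s))
}

# Exact convolution of a piecewise-linear curve (samples cf on a uniform
# grid of step h) with exp(-k t), via the linear recursion
#   y[n+1] = E y[n] + a cf[n] + b cf[n+1],
# where the segment integrals a, b follow from integrating
# (c0 + m s) exp(-k (h - s)) over s in [0, h]. Runs in C through
# stats::filter.
conv_exp_uniform <- function(cf, k, h) {
  n <- length(cf)
  if (n == 0L) return(numeric(0))
  if (k * h < 1e-12) {
    # k -> 0 limit: running trapezoidal integral of the input
    seg <- (cf[-n] + cf[-1]) * h / 2
    return(c(0, cumsum(seg)))
  }
  E <- exp(-k * h)
  i0 <- (1 - E) / k                  # integral of exp(-k(h-s)) ds
  i1 <- (h / k - (1 - E) / k^2)      # integral of s exp(-k(h-s)) ds
  a <- i0 - i1 / h                   # weight on segment-start sample
  b <- i1 / h                        # weight on segment-end sample
  u <- c(0, a * cf[-n] + b * cf[-1])
  as.numeric(stats::filter(u, E, method = "recursive"))
}

#' Frame-average a fine-grid curve
#'
#' Averages a curve sampled on a uniform fine grid over each acquisition
#' frame, matching what a reconstruction integrates over a frame.
#'
#' @param t_s Uniform fine-grid times (s), starting at 0.
#' @param values Curve samples at `t_s`.
#' @param framing A [framing_scheme()]; every frame must be covered by the
#'   fine grid.
#' @return Numeric vector of per-frame averages, one per frame.
#' @export
frame_average <- function(t_s, values, framing) {
  stopifnot_framing(framing)
  if (max(t_s) < max(framing$start_s + framing$duration_s) - 1e-9) {
    stop("fine grid does not cover the framing scheme")
  }
  vapply(seq_len(nrow(framing)), function(i) {
    lo <- framing$start_s[i]
    hi <- lo + framing$duration_s[i]
    sel <- t_s >= lo - 1e-12 & t_s <= hi + 1e-12
    # trapezoidal average over the frame
    tt <- t_s[sel]
    vv <- values[sel]
    sum(diff(tt) * (vv[-length(vv)] + vv[-1]) / 2) / (tt[length(tt)] - tt[1])
  }, numeric(1))
}

#' Forward one-tissue compartment model
#'
#' Tissue concentration under the one-tissue compartment model (1TCM),
#' `C_T(t) = K1 * integral_0^t C_a(s - delay) exp(-k2 (t - s)) ds`,
#' with `K1` the influx (perfusion) rate constant and `k2` the efflux rate
#' constant. For the freely diffusible water tracer, `K1` equals tissue
#' perfusion. Rates are taken per minute at the interface and converted to
#' per-second internally; `k1` uses the reporting unit mL/100 cm^3/min.
#'
#' @param k1 Influx rate constant, mL/100 cm^3/min, >= 0.
#' @param k2 Efflux rate constant, 1/min, > 0.
#' @param delay_s Blood delay between the arterial sampling site and the
#'   tissue (s), >= 0; the input function is shifted later by this amount.
#' @param input Either a function of time in seconds returning kBq/mL
#'   (e.g. [aif_value()] wrapped in a closure) or a two-column object with
#'   times and values to be interpolated.
#' @param framing A [framing_scheme()] defining the output frames.
#' @param fine_step_s Fine integration step (s).
#' @return A tibble with columns `frame`, `mid_time_s`, `duration_s` and
#'   `value` (frame-averaged tissue concentration, kBq/mL).
#' @examples
#' aif <- aif_model()
#' forward_1tcm(3, 0.3, 5, function(t) aif_value(aif, t), framing_scheme())
#' @export
forward_1tcm <- function(k1, k2, delay_s, input, framing = framing_scheme(),
                         fine_step_s = 0.05) {
  if (k1 < 0) stop("`k1` must be non-negative")
  if (k2 <= 0) stop("`k2` must be positive")
  if (delay_s < 0) stop("`delay_s` must be non-negative")
  stopifnot_framing(framing)
  t_end <- total_duration(framing)
  tf <- seq(0, t_end, by = fine_step_s)
  fine <- forward_1tcm_fine(k1, k2, delay_s, input, tf, fine_step_s)
  tibble::tibble(
    frame = framing$frame,
    mid_time_s = framing$mid_time_s,
    duration_s = framing$duration_s,
    value = frame_average(tf, fine, framing)
  )
}

# Fine-grid tissue curve (point values, not frame averages).
forward_1tcm_fine <- function(k1, k2, delay_s, input, tf, fine_step_s) {
  ca <- eval_input(input, tf - delay_s)
  k1_per_s <- k1 / 100 / 60
  k2_per_s <- k2 / 60
  k1_per_s * conv_exp_uniform(ca, k2_per_s, fine_step_s)
}

eval_input <- function(input, t) {
  if (is.function(input)) {
    vals <- input(pmax(t, 0))
    vals[t < 0] <- 0
    return(vals)
  }
  df <- as.data.frame(input)
  if (all(c("mid_time_s", "value") %in% names(df))) {
    tt <- df$mid_time_s
    vv <- df$value
  } else if (ncol(df) >= 2L) {
    tt <- df[[1]]
    vv <- df[[2]]
  } else {
    stop("tabular `input` needs time and value columns")
  }
  out <- stats::approx(tt, vv, xout = t, rule = 2)$y
  out[t < 0] <- 0
  out
}
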