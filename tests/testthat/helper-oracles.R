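# Independent oracles used across tests. Deliberately simple and separate
# from the package's numerical paths.

# Fixed-step RK4 integration of the 1TCM ODE
#   dC/dt = k1' Ca(t - delay) - k2' C,   rates per second,
# evaluated on a uniform grid; returns C at `times` by linear interpolation.
ode_1tcm_oracle <- function(k1_per100_min, k2_per_min, delay_s, aif_fun,
                            times, step = 0.01) {
  k1 <- k1_per100_min / 100 / 60
  k2 <- k2_per_min / 60
  t_end <- max(times)
  tg <- seq(0, t_end, by = step)
  ca <- function(t) if (t < delay_s) 0 else aif_fun(t - delay_s)
  f <- function(t, y) k1 * ca(t) - k2 * y
  y <- numeric(length(tg))
  for (i in seq_len(length(tg) - 1)) {
    t <- tg[i]; yi <- y[i]; h <- step
    d1 <- f(t, yi)
    d2 <- f(t + h / 2, yi + h / 2 * d1)
    d3 <- f(t + h / 2, yi + h / 2 * d2)
    d4 <- f(t + h, yi + h * d3)
    y[i + 1] <- yi + h / 6 * (d1 + 2 * d2 + 2 * d3 + d4)
  }
  stats::approx(tg, y, xout = times)$y
}

# ICC(2,1) from scratch via stats::aov mean squares (independent of the
# package's sums-of-squares route).
icc21_aov_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(
    y = as.vector(m),
    subj = factor(rep(seq_len(n), times = k)),
    meas = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subj + meas, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# small phantom for tests that need full 4D volumes but not the default size
small_phantom <- function() {
  leg_phantom(dim = c(32, 32, 24),
              voxel_mm = c(1.65, 1.65, 1.5),
              leg_center_mm = c(26.4, 26.4), leg_radius_mm = 24,
              tibia_center_mm = c(20, 18), tibia_radius_mm = 3.5,
              fibula_center_mm = c(34, 20), fibula_radius_mm = 2,
              artery_center_mm = c(26.4, 32), artery_radius_mm = 2.5,
              posterior_y_mm = 28,
              malleolus_z_mm = 0, knee_z_mm = 30,
              artery_bifurcation_z_mm = 33)
}
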