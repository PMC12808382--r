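test_that("identical columns give ICC 1 with upper bound 1", {
  m <- cbind(c(1, 2, 3, 5), c(1, 2, 3, 5))
  res <- icc_2_1(m)
  expect_equal(res$icc, 1)
  expect_equal(res$upper, 1)
  expect_equal(res$interpretation, "excellent")
})

test_that("ICC(2,1) matches an independent aov-based computation", {
  withr::with_seed(123, {
    for (i in 1:100) {
      n <- sample(4:20, 1)
      k <- sample(2:5, 1)
      m <- matrix(rnorm(n * k, mean = 3, sd = runif(1, 0.2, 2)), n, k)
      expect_equal(icc_2_1(m)$icc, icc21_aov_oracle(m), tolerance = 1e-10)
    }
  })
})

test_that("a constant offset in one column lowers absolute-agreement ICC", {
  # ratings with a genuine subject effect plus small measurement error
  m <- withr::with_seed(5, {
    subj <- rnorm(10, 3, 1)
    cbind(subj + rnorm(10, 0, 0.1), subj + rnorm(10, 0, 0.1))
  })
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 1
  expect_lt(icc_2_1(shifted)$icc, icc_2_1(m)$icc)
  # consistency form ignores the offset entirely
  expect_equal(icc_2_1(shifted, type = "consistency")$icc,
               icc_2_1(m, type = "consistency")$icc, tolerance = 1e-12)
})

test_that("ICC is invariant to row permutation and affine rescaling", {
  m <- withr::with_seed(6, matrix(rnorm(30, 3), 10, 3))
  base <- icc_2_1(m)$icc
  expect_equal(icc_2_1(m[sample(10), ])$icc, base, tolerance = 1e-12)
  expect_equal(icc_2_1(2.5 * m + 7)$icc, base, tolerance = 1e-12)
})

test_that("constant matrices yield an undefined status instead of an error", {
  res <- icc_2_1(matrix(4, 5, 2))
  expect_equal(res$status, "undefined")
  expect_true(is.na(res$icc))
})

test_that("long-format ratings are pivoted into the subjects-by-measurements matrix", {
  df <- expand.grid(subject = 1:6, measurement = c("r1s1", "r1s2"))
  df$value <- withr::with_seed(7, rnorm(12, 3))
  m <- cbind(df$value[1:6], df$value[7:12])
  expect_equal(icc_2_1(df)$icc, icc_2_1(m)$icc)
  expect_error(icc_2_1(data.frame(a = 1)), "subject")
})

test_that("reliability bands follow the documented half-open convention", {
  expect_equal(interpret_icc(0.95), "excellent")
  expect_equal(interpret_icc(0.4), "poor")
  expect_equal(interpret_icc(0.89), "good")
  expect_equal(interpret_icc(c(0.5, 0.75, 0.9, 0.900001)),
               c("moderate", "good", "good", "excellent"))
  expect_error(interpret_icc(1.2), "lie in")
})

test_that("Bland-Altman bias and limits follow the 1.96 SD rule", {
  eq <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$bias, 0)
  expect_equal(c(eq$loa_lower, eq$loa_upper), c(0, 0))

  x <- c(1, 2, 3)
  off <- bland_altman(x, x + 2)
  expect_equal(off$bias, -2)
  expect_equal(off$sd_diff, 0)
  expect_equal(c(off$loa_lower, off$loa_upper), c(-2, -2))

  d <- bland_altman(c(-1, 0, 1), c(0, 0, 0))
  expect_equal(d$bias, 0)
  expect_equal(d$sd_diff, 1)
  expect_equal(c(d$loa_lower, d$loa_upper), c(-1.96, 1.96))

  expect_error(bland_altman(1:3, 1:4), "differ")
})

test_that("Bland-Altman is antisymmetric under swapping the methods", {
  x <- withr::with_seed(8, rnorm(10, 3))
  y <- withr::with_seed(9, rnorm(10, 3.2))
  ab <- bland_altman(x, y)
  ba <- bland_altman(y, x)
  expect_equal(ba$bias, -ab$bias)
  expect_equal(ba$loa_lower, -ab$loa_upper)
  expect_equal(ba$loa_upper, -ab$loa_lower)
})

test_that("mean CI uses the t quantile", {
  res <- mean_with_ci(c(1, 2, 3))
  expect_equal(res$mean, 2)
  expect_equal(res$upper - res$mean, 4.302653 * (1 / sqrt(3)),
               tolerance = 1e-6)
  expect_equal(res$mean - res$lower, res$upper - res$mean)
  expect_error(mean_with_ci(5), "at least 2")
  const <- mean_with_ci(rep(2, 4))
  expect_equal(c(const$lower, const$upper), c(2, 2))
})

test_that("zero-jitter virtual study returns perfect agreement and is seed-stable", {
  st1 <- virtual_rater_study(n_legs = 3, sphere_sigma_mm = 0,
                             contour_steps = 0, idif_plane_jitter = 0,
                             phantom = small_phantom(),
                             noise = noise_model(0.4), seed = 17)
  expect_true(all(abs(st1$agreement$icc - 1) < 1e-12))
  expect_true(all(st1$agreement$bias == 0))
  st2 <- virtual_rater_study(n_legs = 3, sphere_sigma_mm = 0,
                             contour_steps = 0, idif_plane_jitter = 0,
                             phantom = small_phantom(),
                             noise = noise_model(0.4), seed = 17)
  expect_identical(st1$ratings$k1, st2$ratings$k1)
  expect_error(virtual_rater_study(n_legs = 1), "at least 2")
})

test_that("jittered virtual study tracks the ground-truth perfusion ordering", {
  st <- virtual_rater_study(n_legs = 4, phantom = small_phantom(),
                            noise = noise_model(0.4), seed = 18)
  expect_equal(nrow(st$ratings), 4 * 2 * 2 * 2)
  expect_equal(unique(st$agreement$design), c("intrarater", "interrater"))
  mean_k1 <- tapply(st$ratings$k1, st$ratings$leg, mean)
  truth <- tapply(st$ratings$true_k1, st$ratings$leg, mean)
  expect_equal(order(mean_k1), order(truth))
  expect_s3_class(tidy(st), "tbl_df")
})
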