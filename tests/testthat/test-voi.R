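test_that("lower-leg level interpolates between the landmarks", {
  expect_equal(lower_leg_level(0, 380, 0.6), 228)
  expect_equal(lower_leg_level(10, 50, 0), 10)
  expect_equal(lower_leg_level(10, 50, 1), 50)
  expect_error(lower_leg_level(50, 10), "inverted")
  expect_error(lower_leg_level(0, 100, 1.2), "fraction")
})

test_that("bone exclusion zone equals brute-force distance thresholding", {
  g <- pet_grid(c(20, 18, 12))
  bone <- array(FALSE, dim = g$dim)
  bone[9, 8, 6] <- TRUE
  zone <- bone_exclusion_zone(voi_mask(bone, g), margin_mm = 20)
  # brute force: all voxel centres within 20 mm of the bone voxel centre
  ctr <- c((9 - 0.5) * 1.65, (8 - 0.5) * 1.65, (6 - 0.5) * 1.5)
  brute <- array(FALSE, dim = g$dim)
  for (i in 1:20) for (j in 1:18) for (k in 1:12) {
    d <- sqrt(((i - 0.5) * 1.65 - ctr[1])^2 +
                ((j - 0.5) * 1.65 - ctr[2])^2 +
                ((k - 0.5) * 1.5 - ctr[3])^2)
    brute[i, j, k] <- d <= 20
  }
  expect_identical(zone$mask, brute)
})

test_that("bone exclusion zone limits: zero margin and whole-grid margin", {
  g <- pet_grid(c(10, 10, 8))
  bone <- array(FALSE, dim = g$dim)
  bone[5, 5, 4] <- TRUE
  bv <- voi_mask(bone, g)
  expect_identical(bone_exclusion_zone(bv, 0)$mask, bone)
  diag_mm <- sqrt(sum((g$dim * g$voxel_mm)^2))
  expect_true(all(bone_exclusion_zone(bv, diag_mm)$mask))
})

test_that("contour VOI selects the posterior compartment stack minus the bone zone", {
  ph <- small_phantom()
  lab <- phantom_labels(ph)
  g <- ph$grid
  lvl <- lower_leg_level(ph$malleolus_z_mm, ph$knee_z_mm)
  bone <- voi_mask(lab == 1L | lab == 2L, g)
  zone <- bone_exclusion_zone(bone)
  voi <- muscle_contour_voi(lab, g, lvl, bone_zone = zone)
  expect_true(all(lab[voi$mask] == phantom_label_codes[["posterior"]]))
  expect_false(any(voi$mask & zone$mask))
  # exactly 10 slices (15 mm) occupied
  z_any <- apply(voi$mask, 3, any)
  expect_equal(sum(z_any), 10)
  expect_equal(sum(diff(which(z_any)) == 1), 9)   # consecutive
  expect_equal(voi$provenance, "contour")
  expect_gt(voi_volume_mL(voi), 0)

  one <- muscle_contour_voi(lab, g, lvl, n_slices = 1, bone_zone = zone)
  expect_equal(sum(apply(one$mask, 3, any)), 1)

  # a zone covering everything empties the VOI
  allzone <- voi_mask(array(TRUE, g$dim), g)
  expect_error(muscle_contour_voi(lab, g, lvl, bone_zone = allzone), "empty")
})

test_that("two standard 7.5-mm spheres total 3.5 mL", {
  g <- pet_grid(c(64, 64, 48))
  spheres <- list(sphere_spec(c(30, 50, 30)), sphere_spec(c(70, 50, 30)))
  voi <- sphere_voi(spheres, g)
  continuous <- 2 * (4 / 3) * pi * 7.5^3          # 3534.29 mm^3
  expect_equal(round(continuous / 1000, 1), 3.5)
  # voxel-centre inclusion at 1.65 x 1.65 x 1.5 mm tracks the analytic
  # volume to a few percent, alignment-dependent
  expect_lt(abs(voi_volume_mL(voi) - continuous / 1000) / (continuous / 1000),
            0.03)
  expect_equal(voi$provenance, "spheres")
})

test_that("overlapping spheres union without double counting", {
  g <- pet_grid(c(40, 40, 24))
  apart <- sphere_voi(list(sphere_spec(c(15, 30, 18)),
                           sphere_spec(c(45, 30, 18))), g)
  ontop <- sphere_voi(list(sphere_spec(c(30, 30, 18)),
                           sphere_spec(c(30, 30, 18))), g)
  single <- sphere_voi(sphere_spec(c(30, 30, 18)), g)
  expect_identical(ontop$mask, single$mask)
  expect_equal(sum(apart$mask), 2 * sum(single$mask), tolerance = 0.02)
})

test_that("tiny sphere on a voxel centre selects exactly that voxel", {
  g <- pet_grid(c(10, 10, 10), voxel_mm = c(2, 2, 2))
  voi <- sphere_voi(sphere_spec(c(5, 5, 5), radius_mm = 0.9), g)
  expect_equal(sum(voi$mask), 1)
  expect_true(voi$mask[3, 3, 3])
})

test_that("sphere voxelisation converges to the analytic volume under refinement", {
  vol_at <- function(n, d) {
    g <- pet_grid(c(n, n, n), voxel_mm = rep(d, 3))
    voi_volume_mL(sphere_voi(sphere_spec(rep(n * d / 2, 3)), g)) * 1000
  }
  truth <- (4 / 3) * pi * 7.5^3
  errs <- c(abs(vol_at(16, 2) - truth),
            abs(vol_at(32, 1) - truth),
            abs(vol_at(64, 0.5) - truth))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / truth, 0.02)
})

test_that("sphere centres outside the grid are rejected", {
  g <- pet_grid(c(10, 10, 10))
  expect_error(sphere_voi(sphere_spec(c(100, 5, 5)), g), "outside")
})

test_that("geometric constructions are deterministic and label-local", {
  ph <- small_phantom()
  lab <- phantom_labels(ph)
  g <- ph$grid
  lvl <- lower_leg_level(ph$malleolus_z_mm, ph$knee_z_mm)
  zone <- bone_exclusion_zone(voi_mask(lab == 1L | lab == 2L, g))
  v1 <- muscle_contour_voi(lab, g, lvl, bone_zone = zone)
  v2 <- muscle_contour_voi(lab, g, lvl, bone_zone = zone)
  expect_identical(v1$mask, v2$mask)
  # relabeling an irrelevant label leaves the contour untouched
  lab2 <- lab
  lab2[lab2 == phantom_label_codes[["anterior"]]] <- 9L
  v3 <- muscle_contour_voi(lab2, g, lvl, bone_zone = zone)
  expect_identical(v3$mask, v1$mask)
})

test_that("contour VOI is larger than the combined spheres on the default phantom", {
  ph <- leg_phantom()
  lab <- phantom_labels(ph)
  g <- ph$grid
  lvl <- lower_leg_level(ph$malleolus_z_mm, ph$knee_z_mm)
  zone <- bone_exclusion_zone(voi_mask(lab == 1L | lab == 2L, g))
  contour <- muscle_contour_voi(lab, g, lvl, bone_zone = zone)
  spheres <- sphere_voi(default_sphere_centers(lab, g, lvl), g)
  expect_gt(voi_volume_mL(contour), voi_volume_mL(spheres))
})
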