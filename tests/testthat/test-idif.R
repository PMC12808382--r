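make_toy_scan <- function(values) {
  # values: vector of per-frame artery means for a 4x4x6 toy volume
  g <- pet_grid(c(4, 4, 6), voxel_mm = c(1, 1, 1))
  fr <- framing_scheme(list(c(length(values), 5)))
  data <- array(0, dim = c(g$dim, length(values)))
  lab <- array(0L, dim = g$dim)
  lab[2:3, 2:3, ] <- phantom_label_codes[["artery"]]
  for (f in seq_along(values)) {
    vol <- array(0, dim = g$dim)
    vol[lab == phantom_label_codes[["artery"]]] <- values[f]
    data[, , , f] <- vol
  }
  structure(list(data = data, grid = g, framing = fr, labels = lab),
            class = "pet_scan")
}

test_that("peak frame is the argmax of the region mean, earliest on ties", {
  scan <- make_toy_scan(c(0, 5, 9, 3, 1))
  region <- label_voi(scan$labels, scan$grid, "artery")
  expect_equal(find_peak_frame(scan, region), 3)
  flat <- make_toy_scan(c(2, 2, 2))
  expect_equal(find_peak_frame(flat, label_voi(flat$labels, flat$grid, "artery")), 1)
})

test_that("peak frame of a simulated bolus brackets the true AIF peak", {
  a <- aif_model()
  scan <- simulate_dynamic_scan(phantom = small_phantom(), aif = a,
                                noise = noise_model(0))
  region <- label_voi(scan$labels, scan$grid, "artery")
  pk <- find_peak_frame(scan, region)
  t_peak <- a$t0_s + a$alpha * a$beta_s     # 25 s
  expect_lte(scan$framing$start_s[pk], t_peak)
  expect_gte(scan$framing$start_s[pk] + scan$framing$duration_s[pk], t_peak)
})

test_that("per-plane top-k selection picks the highest-intensity voxels", {
  g <- pet_grid(c(6, 1, 3), voxel_mm = c(1, 1, 1))
  fr <- framing_scheme(list(c(1, 5)))
  data <- array(0, dim = c(g$dim, 1))
  for (k in 1:3) data[, 1, k, 1] <- c(10, 9, 8, 7, 6, 5)
  lab <- array(phantom_label_codes[["artery"]], dim = g$dim)
  scan <- structure(list(data = data, grid = g, framing = fr, labels = lab),
                    class = "pet_scan")
  region <- label_voi(lab, g, "artery")
  sel <- extract_idif(scan, region, start_plane = 1, n_vox = 4, n_planes = 3)
  expect_equal(sum(sel$voi$mask), 12)
  for (k in 1:3) expect_identical(which(sel$voi$mask[, 1, k]), 1:4)
  expect_equal(sel$tac$value, (10 + 9 + 8 + 7) / 4)
})

test_that("default selection takes 4 voxels in each of 10 planes", {
  scan <- simulate_dynamic_scan(noise = noise_model(0))
  region <- label_voi(scan$labels, scan$grid, "artery")
  plane <- locate_start_plane(scan$phantom$artery_bifurcation_z_mm, scan$grid)
  sel <- extract_idif(scan, region, plane)
  expect_equal(sum(sel$voi$mask), 40)
  per_plane <- apply(sel$voi$mask, 3, sum)
  expect_identical(which(per_plane > 0), seq(plane, plane + 9L))
  expect_true(all(per_plane[per_plane > 0] == 4))
  expect_true(all(region$mask[sel$voi$mask]))
})

test_that("noiseless IDIF reproduces the ground-truth arterial curve", {
  scan <- simulate_dynamic_scan(noise = noise_model(0))
  region <- label_voi(scan$labels, scan$grid, "artery")
  plane <- locate_start_plane(scan$phantom$artery_bifurcation_z_mm, scan$grid)
  sel <- extract_idif(scan, region, plane)
  truth <- ground_truth_tac(scan, "artery")
  expect_lt(max(abs(sel$tac$value - truth$value)), 1e-9)
})

test_that("selected voxels dominate unselected in-region voxels at the peak frame", {
  scan <- simulate_dynamic_scan(phantom = small_phantom(),
                                noise = noise_model(0.4), seed = 31)
  region <- label_voi(scan$labels, scan$grid, "artery")
  plane <- locate_start_plane(scan$phantom$artery_bifurcation_z_mm, scan$grid)
  sel <- extract_idif(scan, region, plane, n_planes = 5)
  peak <- scan$data[, , , sel$peak_frame]
  for (k in seq(plane, plane + 4L)) {
    chosen <- peak[, , k][sel$voi$mask[, , k]]
    rest <- peak[, , k][region$mask[, , k] & !sel$voi$mask[, , k]]
    expect_gte(min(chosen), max(rest))
  }
  # idempotent: rerunning with the same peak frame returns the same mask
  sel2 <- extract_idif(scan, region, plane, n_planes = 5,
                       peak_frame = sel$peak_frame)
  expect_identical(sel$voi$mask, sel2$voi$mask)
})

test_that("max-selection on noisy data biases the IDIF peak upward", {
  scans <- lapply(41:45, function(s) {
    simulate_dynamic_scan(phantom = small_phantom(),
                          noise = noise_model(0.05), seed = s)
  })
  region <- label_voi(scans[[1]]$labels, scans[[1]]$grid, "artery")
  plane <- locate_start_plane(scans[[1]]$phantom$artery_bifurcation_z_mm,
                              scans[[1]]$grid)
  truth_peak <- max(ground_truth_tac(scans[[1]], "artery")$value)
  peaks <- vapply(scans, function(s) {
    max(extract_idif(s, region, plane)$tac$value)
  }, numeric(1))
  expect_gt(mean(peaks), truth_peak)
})

test_that("start-plane location maps world offsets to axial indices", {
  g <- pet_grid(c(4, 4, 300))
  # 0-based arithmetic (300 - 30)/1.5 = 180 -> 1-based plane 181
  expect_equal(locate_start_plane(300, g), 181)
  # a coordinate on a plane boundary belongs to the upper plane
  expect_equal(locate_start_plane(300, g, offset_mm = 0), 201)
  expect_error(locate_start_plane(300, g, offset_mm = 400), "outside")
})

test_that("plane shortages are reported with the offending plane", {
  g <- pet_grid(c(2, 2, 4), voxel_mm = c(1, 1, 1))
  fr <- framing_scheme(list(c(1, 5)))
  lab <- array(0L, dim = g$dim)
  lab[1, 1, 1:2] <- phantom_label_codes[["artery"]]   # 1 voxel per plane
  scan <- structure(list(data = array(1, c(g$dim, 1)), grid = g,
                         framing = fr, labels = lab),
                    class = "pet_scan")
  region <- label_voi(lab, g, "artery")
  expect_error(extract_idif(scan, region, 1, n_vox = 4, n_planes = 2),
               "plane 1")
  expect_error(extract_idif(scan, region, 3, n_vox = 1, n_planes = 3),
               "outside")
})
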