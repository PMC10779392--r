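test_that("threshold segmentation is strict and monotone over 7000/7500/8000", {
  set.seed(23)
  ag <- simulate_angiogram(grid = c(30, 30, 30),
                           tube_specs = list(list(axis = 3,
                                                  center = c(15, 15),
                                                  radius = 3.5,
                                                  from = 3, to = 28)),
                           background_level = 6800, noise_sd = 400,
                           seed = 23)
  v <- vapply(c(7000, 7500, 8000), function(th)
    segment_vessels(ag$volume, th)$volume_mm3, numeric(1))
  expect_true(all(diff(v) <= 0))
  for (ax in c("X", "Y", "Z")) {
    a <- vapply(c(7000, 7500, 8000), function(th)
      mip_vessel_area(ag$volume, ax, th), numeric(1))
    expect_true(all(diff(a) <= 0))
  }

  # voxels exactly at the threshold are excluded
  flat <- volume_image(array(7000, c(3, 3, 3)))
  expect_equal(segment_vessels(flat, 7000)$volume_mm3, 0)

  # quiet background below threshold segments nothing
  bg <- simulate_angiogram(background_level = 6000, noise_sd = 100,
                           seed = 1)
  expect_equal(segment_vessels(bg$volume, 7000)$volume_mm3, 0)
})

test_that("tube lumen volume agrees with the analytic cylinder", {
  ag <- simulate_angiogram(grid = c(30, 30, 60),
                           tube_specs = list(list(axis = 3,
                                                  center = c(15, 15),
                                                  radius = 3,
                                                  from = 6, to = 55)),
                           background_level = 6000, noise_sd = 100,
                           seed = 24)
  seg <- segment_vessels(ag$volume, 7000)
  vox_vol <- prod(ag$volume$voxel_dims)
  analytic <- pi * 3^2 * 50 * vox_vol
  expect_lt(abs(seg$volume_mm3 - analytic) / analytic, 0.1)
  expect_equal(seg$volume_mm3, ag$lumen_voxels * vox_vol)
})

test_that("MIP takes per-pixel maxima along the chosen axis", {
  flat <- volume_image(array(4, c(5, 6, 7)))
  expect_true(all(mip(flat, "X") == 4))
  expect_equal(dim(mip(flat, "X")), c(6, 7))
  expect_equal(dim(mip(flat, "Y")), c(5, 7))
  expect_equal(dim(mip(flat, "Z")), c(5, 6))

  toy <- array(1, c(3, 3, 3))
  toy[2, 3, 1] <- 9
  tv <- volume_image(toy)
  for (ax in c("X", "Y", "Z")) {
    proj <- mip(tv, ax)
    expect_equal(sum(proj == 9), 1)
  }
  expect_equal(mip(tv, "X")[3, 1], 9)
  expect_equal(mip(tv, "Y")[2, 1], 9)
  expect_equal(mip(tv, "Z")[2, 3], 9)

  # every MIP pixel dominates every slice along its axis
  set.seed(25)
  rnd <- volume_image(array(stats::runif(60), c(3, 4, 5)))
  pz <- mip(rnd, "Z")
  for (k in 1:5) expect_true(all(pz >= rnd$data[, , k]))
  expect_error(mip(rnd, "W"), "axis")
})

test_that("MIP areas of a z-tube match disk and rectangle geometry", {
  # radius 3.5 rasterises 7 voxels wide, matching the 2r rectangle
  ag <- simulate_angiogram(grid = c(30, 30, 60),
                           tube_specs = list(list(axis = 3,
                                                  center = c(15, 15),
                                                  radius = 3.5,
                                                  from = 6, to = 55)),
                           background_level = 6000, noise_sd = 100,
                           seed = 26)
  vd <- ag$volume$voxel_dims
  az <- mip_vessel_area(ag$volume, "Z", 7000)
  expect_lt(abs(az - pi * 3.5^2 * vd[1] * vd[2]) /
              (pi * 3.5^2 * vd[1] * vd[2]), 0.15)
  ax <- mip_vessel_area(ag$volume, "X", 7000)
  ay <- mip_vessel_area(ag$volume, "Y", 7000)
  rect <- 2 * 3.5 * 50 * vd[1] * vd[3]
  expect_lt(abs(ax - rect) / rect, 0.15)
  expect_lt(abs(ay - rect) / rect, 0.15)
  expect_equal(mip_vessel_area(ag$volume, "Z", 9500), 0)
})

test_that("vessel-brain correlation handles proportional, null and constant cases", {
  # exactly proportional measures -> R2 = 1 in every combination
  brain <- c(400, 420, 440, 460, 480, 500)
  measures <- lapply(brain, function(bv) {
    data.frame(threshold = c(7000, 7500, 8000),
               volume_mm3 = bv * c(0.03, 0.02, 0.01),
               mip_area_x_mm2 = bv * c(3, 2, 1) * 1e-3,
               mip_area_y_mm2 = bv * c(4, 3, 2) * 1e-3,
               mip_area_z_mm2 = bv * c(5, 4, 3) * 1e-3)
  })
  res <- vessel_brain_correlation(measures, brain)
  expect_equal(nrow(res$by_combination), 9L)
  expect_equal(res$by_combination$r_squared, rep(1, 9), tolerance = 1e-12)
  expect_equal(res$summary$mean_r_squared, 1, tolerance = 1e-12)
  expect_equal(res$summary$sd_r_squared, 0, tolerance = 1e-12)

  # independent noise at n = 12 stays below the null 95% bound
  set.seed(27)
  brain12 <- stats::rnorm(12, 450, 30)
  null_measures <- lapply(1:12, function(s)
    data.frame(threshold = c(7000, 7500, 8000),
               volume_mm3 = stats::rnorm(3, 5, 1),
               mip_area_x_mm2 = stats::rnorm(3, 5, 1),
               mip_area_y_mm2 = stats::rnorm(3, 5, 1),
               mip_area_z_mm2 = stats::rnorm(3, 5, 1)))
  res0 <- vessel_brain_correlation(null_measures, brain12)
  # null 95% bound for mean of 9 independent r^2 at n = 12, by simulation
  null_means <- replicate(400, mean(replicate(9,
    stats::cor(stats::rnorm(12), stats::rnorm(12))^2)))
  expect_lt(res0$summary$mean_r_squared,
            stats::quantile(null_means, 0.95) + 0.05)

  # a constant combination is excluded with a warning
  const_measures <- lapply(null_measures, function(m) {
    m$mip_area_z_mm2 <- 4
    m
  })
  w <- capture_warnings(
    resc <- vessel_brain_correlation(const_measures, brain12))
  expect_length(w, 3L)  # one per threshold of the constant axis
  expect_true(all(grepl("constant vessel measure", w)))
  expect_equal(resc$summary$n_combinations, 6L)
  expect_error(vessel_brain_correlation(null_measures[1:2], brain12[1:2]),
               "at least 3")
})
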