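test_that("cohort generation is bit-identical for identical (spec, seed)", {
  spec <- cohort_spec(n_control = 2, n_cko = 2, n_regions = 8,
                      n_frames = 60, seed = 4)
  a <- simulate_bold_cohort(spec)
  b <- simulate_bold_cohort(spec)
  expect_identical(a$series[[3]]$matrix, b$series[[3]]$matrix)
  expect_identical(a$truth$targets, b$truth$targets)
  expect_identical(a$meta, b$meta)
})

test_that("with no effects and no noise the sample connectome approaches C0", {
  spec <- cohort_spec(n_control = 2, n_cko = 2, n_regions = 12,
                      n_frames = 5000, subject_effect_sd = 0,
                      group_effect = 0, noise_sd = 0, seed = 3)
  ch <- simulate_bold_cohort(spec)
  for (s in 1:2) {
    cc <- compute_connectome(ch$series[[s]])
    expect_lt(max(abs(cc$matrix - spec$base_connectome)), 0.05)
    expect_equal(ch$truth$targets[[s]], spec$base_connectome)
  }
})

test_that("study defaults give 12 subjects with 1002-frame series at TR 1.8", {
  spec <- cohort_spec()
  expect_equal(spec$n_control + spec$n_cko, 12L)
  expect_equal(spec$n_frames, 1002L)
  expect_equal(spec$tr, 1.8)
  expect_equal(spec$n_regions, 28L)
  ch <- simulate_bold_cohort(cohort_spec(n_frames = 120, seed = 8))
  expect_length(ch$series, 12L)
  expect_equal(table(ch$meta$group)[["control"]], 5L)
  expect_equal(table(ch$meta$group)[["cko"]], 7L)
  expect_true(all(vapply(ch$series, function(s) nrow(s$matrix),
                         numeric(1)) == 120))
})

test_that("planted group effect raises exactly the planted edges of the target", {
  spec <- cohort_spec(n_control = 2, n_cko = 2, n_regions = 10,
                      n_frames = 50, subject_effect_sd = 0,
                      group_effect = 0.3, noise_sd = 0, seed = 5)
  ch <- simulate_bold_cohort(spec)
  idx <- edge_index_table(10)
  ctrl_t <- ch$truth$targets[[1]]
  cko_t <- ch$truth$targets[[3]]
  delta <- (cko_t - ctrl_t)[idx]
  on_planted <- seq_along(delta) %in% spec$group_edges
  expect_true(all(delta[on_planted] > 0.1))
  expect_lt(max(abs(delta[!on_planted])), 0.1)
})

test_that("increasing the group effect never loses planted-edge recoveries", {
  recovered <- vapply(c(0.15, 0.3, 0.45), function(delta) {
    spec <- cohort_spec(n_control = 6, n_cko = 6, n_regions = 16,
                        n_frames = 300, group_effect = delta, seed = 9)
    ch <- simulate_bold_cohort(spec)
    cc <- lapply(ch$series, compute_connectome)
    net <- group_discriminative_edges(cc, threshold = 0.2)
    length(intersect(net$edges$edge, ch$truth$group_edges))
  }, numeric(1))
  expect_true(all(diff(recovered) >= 0))
})

test_that("correlation repair yields a valid correlation matrix", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.9
  m[1, 3] <- m[3, 1] <- 0.9
  m[2, 3] <- m[3, 2] <- -0.9  # not positive semi-definite
  r <- project_to_correlation(m)
  expect_equal(diag(r), rep(1, 3))
  expect_true(all(eigen(r, symmetric = TRUE)$values > 0))
  expect_true(all(abs(r) <= 1 + 1e-12))
  # an already-valid matrix passes through unchanged
  ok <- diag(3); ok[1, 2] <- ok[2, 1] <- 0.5
  expect_equal(project_to_correlation(ok), ok, tolerance = 1e-8)
})

test_that("atlas phantom has mirrored labels and exact stored truth", {
  ph <- make_atlas_phantom(n_control = 2, n_cko = 2, seed = 6)
  labs <- ph$atlases[[1]]$labels$data
  expect_equal(sort(unique(as.integer(labs[labs > 0]))), 1:28)
  v <- region_volumes(ph$atlases[[1]]$labels, ph$region_table,
                      subject = "sub01")
  truth1 <- ph$truth_volumes[ph$truth_volumes$subject == "sub01", ]
  expect_identical(v$table$volume_mm3, truth1$volume_mm3)

  # no scaling, no jitter -> identical volumes for every subject
  ph0 <- make_atlas_phantom(n_control = 2, n_cko = 2, jitter_sd = 0,
                            subject_scale_sd = 0, seed = 6)
  vols <- matrix(ph0$truth_volumes$volume_mm3, ncol = 4)
  expect_true(all(vols == vols[, 1]))
})

test_that("a 1.2x scaled phantom region measures 1.2x within voxel rounding", {
  enl <- rep(1, 28)
  enl[c(14, 28)] <- 1.2
  ph <- make_atlas_phantom(n_control = 2, n_cko = 2,
                           group_scalings = list(control = rep(1, 28),
                                                 cko = enl),
                           jitter_sd = 0, subject_scale_sd = 0, seed = 2)
  tv <- ph$truth_volumes
  ctrl <- tv$volume_mm3[tv$subject == "sub01" & tv$region == 14]
  cko <- tv$volume_mm3[tv$subject == "sub03" & tv$region == 14]
  vox <- prod(ph$atlases[[1]]$labels$voxel_dims)
  expect_lt(abs(cko / ctrl - 1.2), 1.5 * vox / ctrl + 1e-9)
})

test_that("angiogram truth matches analytic cylinder and tubes are additive", {
  one <- simulate_angiogram(grid = c(40, 40, 60),
                            tube_specs = list(list(axis = 3,
                                                   center = c(20, 20),
                                                   radius = 3,
                                                   from = 5, to = 54)),
                            seed = 7)
  expect_lt(abs(one$lumen_voxels - pi * 3^2 * 50) / (pi * 3^2 * 50), 0.1)

  two <- simulate_angiogram(grid = c(40, 40, 60),
                            tube_specs = list(
                              list(axis = 3, center = c(10, 10),
                                   radius = 2, from = 5, to = 24),
                              list(axis = 1, center = c(30, 30),
                                   radius = 2, from = 3, to = 30)),
                            seed = 7)
  ta <- simulate_angiogram(grid = c(40, 40, 60),
                           tube_specs = list(list(axis = 3,
                                                  center = c(10, 10),
                                                  radius = 2,
                                                  from = 5, to = 24)),
                           seed = 7)
  tb <- simulate_angiogram(grid = c(40, 40, 60),
                           tube_specs = list(list(axis = 1,
                                                  center = c(30, 30),
                                                  radius = 2,
                                                  from = 3, to = 30)),
                           seed = 7)
  expect_equal(two$lumen_voxels, ta$lumen_voxels + tb$lumen_voxels)

  empty <- simulate_angiogram(background_level = 6000, noise_sd = 100,
                              seed = 1)
  expect_equal(segment_vessels(empty$volume, 7000)$volume_mm3, 0)
  expect_error(simulate_angiogram(background_level = 7000,
                                  vessel_level = 6000), "exceed")
})

test_that("morphometry samples honour means, sd and seed contracts", {
  z <- simulate_morphometry(10, 9, sd = 0, n_per_group = 5, seed = 1)
  expect_equal(z$control, rep(10, 5))
  expect_equal(z$ko, rep(9, 5))
  a <- simulate_morphometry(10, 9, 1, 30, seed = 2)
  b <- simulate_morphometry(10, 9, 1, 30, seed = 2)
  expect_identical(a, b)
  expect_error(simulate_morphometry(10, 9, 1, 1), "at least 2")
  expect_error(simulate_morphometry(10, 9, -1, 5), ">= 0")
})
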