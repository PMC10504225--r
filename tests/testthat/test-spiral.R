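# Spiral frame, angular unwrapping, and width/thickness morphometry.

test_that("frames normalise their basis and validate handedness", {
  fr <- spiral_frame(c(0, 0, 0), axis_unit = c(0, 0, 2),
                     zero_angle_unit = c(2, 0, 1), handedness = 1)
  expect_equal(sum(fr$axis_unit^2), 1)
  expect_equal(sum(fr$zero_angle_unit^2), 1)
  expect_equal(sum(fr$axis_unit * fr$zero_angle_unit), 0)
  expect_error(spiral_frame(c(0, 0, 0), zero_angle_unit = c(0, 0, 1)),
               "parallel")
  expect_error(spiral_frame(c(0, 0, 0), handedness = 2), "handedness")
})

test_that("angles unwrap across turns using the pitch", {
  fr <- spiral_frame(c(0, 0, 0), pitch_um_per_turn = 300,
                     base_offset_um = 0)
  expect_equal(angular_coordinate(c(100, 0, 0), fr), 0)
  expect_equal(angular_coordinate(c(100, 0, 300), fr), 360)
  expect_equal(angular_coordinate(c(0, 100, 75), fr), 90)
  expect_equal(angular_coordinate(c(0, 100, 435), fr), 450)
  expect_error(angular_coordinate(c(0, 0, 10), fr), "axis")
})

test_that("phantom angles are recovered within 3 degrees for 99% of voxels", {
  ph <- tiny_phantom()
  tr <- ph$truth
  gt <- phantom_material_mask(tr)
  co <- oslmorph:::spiral_coords(gt, tr$frame)
  idx <- co$idx
  th_true <- co$phi + 360 * (tr$turn[idx] - 1L)
  expect_gte(mean(abs(co$theta - th_true) <= 3), 0.99)
})

test_that("the pitch and base offset are estimated from the mask", {
  ph <- tiny_phantom()
  gt <- phantom_material_mask(ph$truth)
  bare <- spiral_frame(ph$truth$frame$center_um)
  est <- estimate_pitch(gt, bare)
  expect_equal(est$pitch_um_per_turn,
               ph$truth$config$pitch_um_per_turn, tolerance = 0.02)
  expect_lt(abs(est$base_offset_um - ph$truth$frame$base_offset_um), 25)
  # a sub-turn structure cannot be unwrapped
  sl <- slab_mask()
  expect_error(estimate_pitch(sl, spiral_frame(c(30, 30, 10))),
               "more than one full turn")
})

test_that("frame fitting recovers the construction centre and axis", {
  ph <- tiny_phantom()
  tr <- ph$truth
  gt <- phantom_material_mask(tr)
  fit <- fit_spiral_frame(gt)
  vox <- tr$config$voxel_size_um
  expect_lt(sqrt(sum((fit$center_um - tr$frame$center_um)^2)), 2 * vox)
  ang <- acos(abs(sum(fit$axis_unit * tr$frame$axis_unit))) * 180 / pi
  expect_lt(ang, 2)
  expect_equal(fit$handedness, tr$frame$handedness)
  # landmarks pass through after normalisation
  lm <- fit_spiral_frame(gt, landmarks = list(center = c(1, 2, 3),
                                              axis = c(0, 0, 5)))
  expect_equal(lm$center_um, c(1, 2, 3))
  expect_equal(lm$axis_unit, c(0, 0, 1))
  # a flat slab is rejected, not silently fitted
  big_slab <- slab_mask(nx = 80, ny = 80, nz = 16, z0 = 6, z1 = 10)
  expect_error(fit_spiral_frame(big_slab))
})

test_that("width is the radial extent of the largest component in the slab", {
  # annulus sector: inner radius 400, outer 2200, voxel 20
  n <- 240L
  ctr <- (n + 1) / 2 * 20
  v <- array(FALSE, c(n, n, 5))
  ii <- expand.grid(x = seq_len(n), y = seq_len(n))
  rho <- sqrt(((ii$x - 1) * 20 - ctr)^2 + ((ii$y - 1) * 20 - ctr)^2)
  phi <- atan2((ii$y - 1) * 20 - ctr, (ii$x - 1) * 20 - ctr) * 180 / pi
  hit <- rho >= 400 & rho <= 2200 & phi >= -10 & phi <= 10
  for (k in 2:4) v[cbind(ii$x[hit], ii$y[hit], k)] <- TRUE
  # a disconnected speck inside the modiolar hole, within the same
  # angular slab, must not widen the measure
  v[132, 121, 3] <- TRUE
  m <- binary_mask(v, 20)
  fr <- spiral_frame(c(ctr, ctr, 40))
  w <- width_at_angle(m, fr, 0, delta_deg = 8)
  expect_lt(abs(w - 1800), 21)
  expect_error(width_at_angle(m, fr, 90), "no material")
})

test_that("thickness spans the plate assembly, outer face to outer face", {
  # two 25 um slabs around a 50 um gap at 5 um voxels
  v <- array(FALSE, c(60, 60, 40))
  v[5:55, 5:55, 10:14] <- TRUE   # lower plate: 25 um
  v[5:55, 5:55, 25:29] <- TRUE   # upper plate; gap 50 um
  m <- binary_mask(v, 5)
  fr <- spiral_frame(c(150, 150, 200))
  for (rp in c("lateral", "middle", "medial"))
    expect_equal(thickness_at(m, fr, 0, rp), 100, tolerance = 5)
  # a single solid slab measures its own height exactly
  v2 <- array(FALSE, c(60, 60, 20))
  v2[5:55, 5:55, 8:12] <- TRUE
  m2 <- binary_mask(v2, 5)
  expect_equal(thickness_at(m2, spiral_frame(c(150, 150, 100)), 0, "middle"),
               25, tolerance = 5)
})

test_that("profiles sample inclusively, flag gaps, and follow the taper", {
  ph <- tiny_phantom()
  tr <- ph$truth
  gt <- phantom_material_mask(tr)
  rg <- partition_regions(gt, tr$frame, c(360, 630))
  pr <- spiral_profile(gt, tr$frame, step_deg = 45, regions = rg)
  expect_equal(nrow(pr$samples), 17)   # 0 to 720 inclusive
  expect_s3_class(pr, "osl_profile")
  d <- pr$samples[pr$samples$defined, ]
  vox <- tr$config$voxel_size_um
  expect_lt(abs(d$width_um[d$theta_deg == 0] - tr$config$width_base_um),
            2 * vox)
  expect_lt(abs(d$width_um[d$theta_deg == 720] - tr$config$width_apex_um),
            2 * vox)
  expect_lte(cor(d$theta_deg, d$width_um, method = "spearman"), -0.95)
  expect_true(all(c("basal", "middle", "apex") %in% pr$summary$region))
})

test_that("a constant-width sweep has near-zero width spread", {
  ph <- generate_phantom(phantom_config(
    voxel_size_um = 10, turns_deg = 400, width_base_um = 300,
    width_apex_um = 300, r_inner_base_um = 150, r_inner_apex_um = 150,
    pitch_um_per_turn = 300, pore_fraction_vp = 0, pore_fraction_tp = 0,
    pillar_density_per_deg = 0, habenular_period_deg = 0,
    speck_count = 0, noise_sd = 0, seed = 3))
  gt <- phantom_material_mask(ph$truth)
  pr <- spiral_profile(gt, ph$truth$frame, step_deg = 45)
  expect_lte(pr$summary$width_um_sd[1], 10)
})

test_that("measurements are invariant under rotating the frame with the query", {
  ph <- micro_solid()
  gt <- phantom_material_mask(ph$truth)
  fr <- ph$truth$frame
  rot <- 30 * pi / 180
  fr_rot <- spiral_frame(fr$center_um, fr$axis_unit,
                         zero_angle_unit = c(cos(rot), sin(rot), 0),
                         handedness = fr$handedness,
                         pitch_um_per_turn = fr$pitch_um_per_turn,
                         base_offset_um = fr$base_offset_um)
  w0 <- width_at_angle(gt, fr, 90)
  w1 <- width_at_angle(gt, fr_rot, 60)
  expect_equal(w0, w1, tolerance = 1e-9)
})
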