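# The filled-envelope porosity statistic: formula, morphological
# envelope construction, and plate-level measurement.

test_that("the porosity formula is evaluated exactly with documented clamping", {
  expect_equal(porosity(1, 1), 0)
  expect_equal(porosity(0.31, 1), 69)
  expect_equal(porosity(0, 5), 100)
  expect_warning(p <- porosity(1.004, 1), "clamped")
  expect_equal(p, 0)
  expect_error(porosity(1.1, 1), "pipeline fault")
  expect_error(porosity(1, 0), "positive")
  expect_error(porosity(-1, 1), "non-negative")
})

test_that("ball closing is a no-op on a pore-free slab", {
  m <- slab_mask()
  env <- fill_envelope(m, 6)
  expect_identical(env$values, m$values)
})

test_that("ball closing fills small pores and leaves large ones open", {
  m <- slab_mask(nx = 120, ny = 120,
                 pores = data.frame(x = c(35, 60, 90), y = c(40, 80, 50),
                                    r = 4))
  full <- slab_mask(nx = 120, ny = 120)
  env <- fill_envelope(m, 6)
  # interior slab layers are restored flush; the shallow mouth dimple
  # of the rolling ball keeps the total within half a percent
  expect_true(all(env$values[, , 10:11] == full$values[, , 10:11]))
  expect_lt((sum(full$values) - sum(env$values)) / sum(full$values), 0.005)
  # a pore wider than the ball is not filled (documented, not an error)
  mbig <- slab_mask(nx = 120, ny = 120,
                    pores = data.frame(x = 60, y = 60, r = 10))
  envbig <- fill_envelope(mbig, 6)
  expect_false(envbig$values[60, 60, 10])
})

test_that("closing is extensive, idempotent, and monotone in the radius", {
  m <- slab_mask(nx = 80, ny = 80,
                 pores = data.frame(x = c(30, 55), y = c(30, 55), r = c(3, 5)))
  e6 <- fill_envelope(m, 6)
  expect_true(all(e6$values[m$values]))
  expect_identical(fill_envelope(e6, 6)$values, e6$values)
  e4 <- fill_envelope(m, 4)
  e8 <- fill_envelope(m, 8)
  expect_true(all(e6$values[e4$values]))
  expect_true(all(e8$values[e6$values]))
})

test_that("a closing that bridges onto the other structure is rejected", {
  # U-channel: a large ball fills the channel, swallowing the slab
  # that sits inside it
  v <- array(FALSE, c(40, 40, 30))
  v[5:35, 5:35, 5:8] <- TRUE     # floor
  v[5:8, 5:35, 5:24] <- TRUE     # wall
  v[32:35, 5:35, 5:24] <- TRUE   # wall
  other <- array(FALSE, c(40, 40, 30))
  other[15:25, 10:30, 14:17] <- TRUE
  m <- binary_mask(v, 1)
  ex <- binary_mask(other, 1)
  e_small <- fill_envelope(m, 4, exclusion_mask = ex)
  expect_false(any(e_small$values & ex$values))
  expect_error(fill_envelope(m, 14, exclusion_mask = ex), "merges")
})

test_that("the height-field wrap reconstructs a tilted pored slab exactly", {
  # staircase ramp: top surface rises one voxel every 6 columns
  nx <- 72; ny <- 48; nz <- 30
  v <- array(FALSE, c(nx, ny, nz))
  for (i in seq_len(nx)) {
    z0 <- 6 + (i - 1) %/% 6
    v[i, 3:(ny - 2), z0:(z0 + 4)] <- TRUE
  }
  full <- v
  ii <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  for (p in list(c(25, 20, 5), c(45, 30, 6))) {
    hit <- (ii$x - p[1])^2 + (ii$y - p[2])^2 <= p[3]^2
    for (k in seq_len(nz)) {
      pg <- v[, , k]; pg[cbind(ii$x[hit], ii$y[hit])] <- FALSE
      v[, , k] <- pg
    }
  }
  env <- fill_envelope(binary_mask(v, 1), 15, method = "plate")
  agree <- mean(env$values == full)
  expect_gte(agree, 0.995)
  expect_true(all(env$values[v]))  # extensive
  expect_identical(fill_envelope(env, 15, method = "plate")$values,
                   env$values)    # idempotent
})

test_that("plate porosity matches voxel counts on a constructed slab", {
  m <- slab_mask(nx = 120, ny = 120,
                 pores = data.frame(x = c(30, 60, 90, 45, 75),
                                    y = c(30, 80, 45, 60, 95),
                                    r = c(4, 4, 3, 4, 3)))
  res <- plate_porosity(m, regions = NULL, closing_radius_um = 8,
                        plate = "slab", envelope_method = "plate")
  expect_s3_class(res, "porosity_result")
  expect_equal(res$p_percent, res$p_voxel_percent, tolerance = 0.02)
  full <- slab_mask(nx = 120, ny = 120)
  p_true <- 100 * (sum(full$values) - sum(m$values)) / sum(full$values)
  expect_lt(abs(res$p_percent - p_true), 1)
})

test_that("a solid phantom plate reports porosity at most 1 percent", {
  tr <- micro_solid()$truth
  vp <- phantom_plate_mask(tr, "vp")
  rg <- phantom_region_partition(tr)
  res <- plate_porosity(vp, rg, closing_radius_um = 40, plate = "vp",
                        envelope_method = "plate")
  expect_true(all(res$p_percent <= 1))
})

test_that("higher pore density yields strictly higher recovered porosity", {
  mk <- function(f) generate_phantom(phantom_config(
    voxel_size_um = 10, turns_deg = 380, width_base_um = 300,
    width_apex_um = 240, r_inner_base_um = 160, r_inner_apex_um = 140,
    pitch_um_per_turn = 300, pore_fraction_vp = f, pore_fraction_tp = f,
    pore_radius_um_range = c(24, 30), speck_count = 0, noise_sd = 0,
    seed = 31))
  p_of <- function(f) {
    tr <- mk(f)$truth
    vp <- phantom_plate_mask(tr, "vp")
    plate_porosity(vp, NULL, closing_radius_um = 75, plate = "vp",
                   envelope_method = "plate")$p_percent
  }
  expect_lt(p_of(0.25), p_of(0.45))
})
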