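# Synthetic spiral-lamina phantom: construction, determinism, and the
# voxel-count porosity oracle.

test_that("generation is bit-identical for a fixed seed", {
  cfg <- phantom_config(voxel_size_um = 12, turns_deg = 380,
                        width_base_um = 300, width_apex_um = 240,
                        r_inner_base_um = 160, r_inner_apex_um = 140,
                        pitch_um_per_turn = 300,
                        pore_fraction_vp = 0.3, pore_fraction_tp = 0.3,
                        pore_radius_um_range = c(24, 30),
                        speck_count = 5, seed = 99)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$truth$label, b$truth$label)
  expect_identical(a$truth$true_porosity, b$truth$true_porosity)
})

test_that("a pore-free, pillar-free phantom has material equal to its envelope", {
  tr <- micro_solid()$truth
  expect_identical(tr$label, tr$envelope)
  expect_true(all(tr$true_porosity$porosity_percent[
    tr$true_porosity$n_envelope > 0] == 0))
  expect_equal(oracle_porosity(tr, "vp", "basal"), 0)
})

test_that("rejection sampling hits the target pore fraction within 1 point", {
  tr <- tiny_phantom()$truth
  for (pl in c("vp", "tp")) {
    target <- if (pl == "vp") tr$config$pore_fraction_vp else
      tr$config$pore_fraction_tp
    got <- oracle_porosity(tr, pl, "all") / 100
    expect_lt(abs(got - target), 0.01)
  }
})

test_that("region labels partition the material and follow the bounds", {
  tr <- tiny_phantom()$truth
  mat <- tr$label > 0L
  expect_true(all(tr$region[mat] %in% 1:3))
  expect_true(all(tr$region[!mat & tr$envelope == 0L] == 0L))
  # angular bounds respected: apex label only beyond the second bound
  idx <- which(tr$label > 0L & tr$region == 3L, arr.ind = TRUE)
  th <- angular_coordinate((idx - 1) * tr$config$voxel_size_um, tr$frame)
  expect_true(all(th >= tr$config$region_bounds_deg[2] - 3))
})

test_that("the construction width profile matches the configured taper", {
  tr <- micro_solid()$truth
  pf <- tr$profile_true
  expect_equal(pf$width_um[pf$theta_deg == 0], tr$config$width_base_um)
  expect_equal(pf$width_um[pf$theta_deg == tr$config$turns_deg],
               tr$config$width_apex_um)
  expect_equal(unique(pf$thickness_um),
               2 * tr$config$plate_thickness_um + tr$config$gap_um)
})

test_that("lattice-unresolvable geometry is rejected with the offending parameter", {
  expect_error(phantom_config(voxel_size_um = 20, plate_thickness_um = 25),
               "plate_thickness_um")
  expect_error(phantom_config(voxel_size_um = 10, gap_um = 12), "gap_um")
  expect_error(phantom_config(pitch_um_per_turn = 90), "clearance")
  expect_error(phantom_config(pore_fraction_vp = 1.2), "pore fraction")
})

test_that("the porosity oracle is plain voxel arithmetic", {
  # hand-built ground truth: 1000 envelope voxels, 690 material
  lab <- array(0L, c(10, 10, 12))
  env <- array(0L, c(10, 10, 12))
  env[, , 1:10] <- 1L                # 1000 vp envelope voxels
  lab[, , 1:7] <- 1L                 # 700 material ...
  lab[1:10, 1, 7] <- 0L              # ... minus 10 -> 690
  reg <- array(0L, c(10, 10, 12))
  reg[env == 1L] <- 1L
  fake <- structure(list(label = lab, envelope = env, region = reg),
                    class = "phantom_truth")
  expect_equal(oracle_porosity(fake, "vp", "basal"), 31)
  expect_equal(oracle_porosity(fake, "vp", "all"), 31)
  expect_error(oracle_porosity(fake, "tp", "basal"), "empty")
})
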