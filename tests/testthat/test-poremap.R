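# Pore space extraction and the radial/angular pore-distribution map.

test_that("a solid plate has an empty pore space", {
  m <- slab_mask()
  ps <- pore_space(m, m)
  expect_equal(sum(ps$mask$values), 0)
  expect_equal(ps$n_pores, 0)
})

test_that("disjoint pores are counted as separate components", {
  full <- slab_mask(nx = 80, ny = 80)
  pored <- slab_mask(nx = 80, ny = 80,
                     pores = data.frame(x = c(20, 40, 60),
                                        y = c(20, 50, 30), r = 4))
  ps <- pore_space(pored, full)
  expect_equal(ps$n_pores, 3)
  expect_equal(sum(ps$mask$values), sum(full$values) - sum(pored$values))
  expect_error(pore_space(full, pored), "does not contain")
})

test_that("phantom pore voxels equal envelope minus material exactly", {
  tr <- tiny_phantom()$truth
  vp <- phantom_plate_mask(tr, "vp")
  env <- phantom_plate_mask(tr, "vp", envelope = TRUE)
  ps <- pore_space(vp, env)
  expect_equal(sum(ps$mask$values), sum(env$values) - sum(vp$values))
})

test_that("band pore voxels conserve the total and fractions stay in range", {
  tr <- tiny_phantom()$truth
  vp <- phantom_plate_mask(tr, "vp")
  env <- phantom_plate_mask(tr, "vp", envelope = TRUE)
  ps <- pore_space(vp, env)
  rg <- phantom_region_partition(tr)
  pm <- radial_pore_fraction(ps, env, tr$frame, n_bands = 3, regions = rg)
  expect_s3_class(pm, "pore_map")
  expect_equal(sum(pm$pore_voxels), sum(ps$mask$values))
  expect_equal(sum(pm$envelope_voxels), sum(env$values))
  ok <- !is.na(pm$pore_fraction)
  expect_true(all(pm$pore_fraction[ok] >= 0 & pm$pore_fraction[ok] <= 1))
  expect_setequal(unique(pm$band), c("medial", "middle", "lateral"))
})

test_that("whole-plate pore fraction agrees with the voxel-count oracle", {
  tr <- tiny_phantom()$truth
  for (pl in c("vp", "tp")) {
    pmask <- phantom_plate_mask(tr, pl)
    env <- phantom_plate_mask(tr, pl, envelope = TRUE)
    ps <- pore_space(pmask, env)
    pm <- radial_pore_fraction(ps, env, tr$frame, n_bands = 3)
    whole <- 100 * sum(pm$pore_voxels) / sum(pm$envelope_voxels)
    expect_lt(abs(whole - oracle_porosity(tr, pl, "all")), 0.5)
  }
})

test_that("a middle-heavy phantom concentrates pores in the middle band", {
  ph <- generate_phantom(phantom_config(
    voxel_size_um = 8, turns_deg = 720, width_base_um = 400,
    width_apex_um = 250, r_inner_base_um = 180, r_inner_apex_um = 140,
    pitch_um_per_turn = 360, pore_fraction_vp = 0.35,
    pore_fraction_tp = 0.35, pore_radius_um_range = c(20, 28),
    pore_radial_bias = "middle-heavy", habenular_period_deg = 0,
    speck_count = 0, seed = 17))
  tr <- ph$truth
  vp <- phantom_plate_mask(tr, "vp")
  env <- phantom_plate_mask(tr, "vp", envelope = TRUE)
  ps <- pore_space(vp, env)
  rg <- phantom_region_partition(tr)
  pm <- radial_pore_fraction(ps, env, tr$frame, n_bands = 3, regions = rg)
  basal <- pm[pm$sector == "basal", ]
  expect_gt(basal$pore_fraction[basal$band == "middle"],
            max(basal$pore_fraction[basal$band != "middle"]))
})
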