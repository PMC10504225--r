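# Watertight surface extraction, divergence-theorem volumes, and
# volume-preserving decimation.

test_that("divergence-theorem volume of a hand-built unit cube is exact", {
  V <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  # 12 triangles, outward orientation
  F <- rbind(
    c(1, 7, 3), c(1, 5, 7),  # x = 0 face (outward -x)
    c(2, 4, 8), c(2, 8, 6),  # x = 1 (+x)
    c(1, 2, 6), c(1, 6, 5),  # y = 0 (-y)
    c(3, 8, 4), c(3, 7, 8),  # y = 1 (+y)
    c(1, 3, 4), c(1, 4, 2),  # z = 0 (-z)
    c(5, 6, 8), c(5, 8, 7))  # z = 1 (+z)
  m <- surface_mesh(V, F)
  expect_true(mesh_status(m)$closed)
  expect_equal(mesh_volume(m), 1, tolerance = 1e-12)
  # translation invariance far from the origin
  m2 <- surface_mesh(sweep(V, 2, c(1e6, 1e6, 1e6), "+"), F)
  expect_equal(mesh_volume(m2), 1, tolerance = 1e-6)
})

test_that("a single voxel meshes to its voxel volume", {
  v <- array(FALSE, c(3, 3, 3)); v[2, 2, 2] <- TRUE
  m <- extract_surface(binary_mask(v, 2.5))
  expect_true(mesh_status(m)$closed)
  expect_equal(mesh_volume(m), 2.5^3, tolerance = 0.35 * 2.5^3)
})

test_that("cube and sphere volumes match the analytic values", {
  v <- array(FALSE, c(44, 44, 44)); v[3:42, 3:42, 3:42] <- TRUE
  vol <- mesh_volume(extract_surface(binary_mask(v, 2.5)))
  expect_lt(abs(vol - 1e6) / 1e6, 0.01)
  sp <- sphere_mask(25)
  vol_s <- mesh_volume(extract_surface(sp))
  expect_lt(abs(vol_s - 4 / 3 * pi * 25^3) / (4 / 3 * pi * 25^3), 0.02)
})

test_that("mesh volume agrees with the voxel-count oracle on a random blob", {
  set.seed(5)
  v <- array(FALSE, c(40, 40, 40))
  for (i in 1:12) {
    c0 <- sample(8:32, 3, replace = TRUE)
    r <- sample(4:8, 1)
    idx <- as.matrix(expand.grid(1:40, 1:40, 1:40))
    hit <- rowSums(sweep(idx, 2, c0)^2) <= r^2
    v[idx[hit, ]] <- TRUE
  }
  m <- binary_mask(v, 3)
  vol <- mesh_volume(extract_surface(m))
  expect_lt(abs(vol - sum(v) * 27) / (sum(v) * 27), 0.015)
})

test_that("masks touching the grid boundary still yield a closed surface", {
  v <- array(TRUE, c(6, 6, 6))
  expect_message(m <- extract_surface(binary_mask(v, 1)), "boundary")
  expect_true(mesh_status(m)$closed)
  expect_equal(mesh_volume(m), 216, tolerance = 1e-9)
})

test_that("edge-only voxel contacts are repaired into a manifold surface", {
  v <- array(FALSE, c(6, 6, 6))
  v[2, 2, 2:4] <- TRUE
  v[3, 3, 2:4] <- TRUE  # touches the first bar only along an edge
  expect_message(m <- extract_surface(binary_mask(v, 1)), "contacts")
  expect_true(mesh_status(m)$closed)
  expect_equal(mesh_volume(m), 6, tolerance = 3)  # +/- repaired voxels
})

test_that("open meshes are rejected with the defect named", {
  sp <- extract_surface(sphere_mask(8))
  open <- surface_mesh(sp$vertices, sp$triangles[-1, ])
  expect_error(mesh_volume(open), "boundary edge")
})

test_that("decimation preserves closedness and volume", {
  sp <- extract_surface(sphere_mask(25))
  expect_identical(simplify_mesh(sp, 1), sp)
  dec <- simplify_mesh(sp, 0.3)
  expect_true(mesh_status(dec)$closed)
  expect_lte(nrow(dec$triangles), 0.35 * nrow(sp$triangles))
  expect_lt(abs(mesh_volume(dec) - mesh_volume(sp)) / mesh_volume(sp), 0.01)
  expect_error(simplify_mesh(sp, 0), "fraction")
})

test_that("binary STL round-trips through the package reader", {
  sp <- extract_surface(sphere_mask(6, voxel_size_um = 2.5))
  path <- file.path(tempdir(), "sphere.stl")
  write_stl(sp, path)
  back <- read_stl(path)
  expect_equal(nrow(back$triangles), nrow(sp$triangles))
  expect_true(mesh_status(back)$closed)
  expect_equal(mesh_volume(back), mesh_volume(sp), tolerance = 1e-5)
  unlink(path)
})
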