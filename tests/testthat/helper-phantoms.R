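# Shared synthetic fixtures, generated once per test run and cached.
# Sizes are kept small enough for a single-CPU run while preserving
# every structural feature (two plates, taper, pores, pillars,
# habenular openings, noise, specks).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, fn(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small two-turn lamina with pores, pillars, openings, noise, specks
tiny_phantom <- function() cached("tiny", function() {
  generate_phantom(phantom_config(
    voxel_size_um = 8, turns_deg = 720,
    width_base_um = 500, width_apex_um = 250,
    r_inner_base_um = 220, r_inner_apex_um = 160,
    pitch_um_per_turn = 360,
    pore_fraction_vp = 0.40, pore_fraction_tp = 0.50,
    pore_radius_um_range = c(20, 28),
    speck_count = 8, seed = 42))
})

# very small solid (pore-free) lamina
micro_solid <- function() cached("micro_solid", function() {
  generate_phantom(phantom_config(
    voxel_size_um = 10, turns_deg = 400,
    width_base_um = 300, width_apex_um = 220,
    r_inner_base_um = 150, r_inner_apex_um = 120,
    pitch_um_per_turn = 300,
    pore_fraction_vp = 0, pore_fraction_tp = 0,
    pillar_density_per_deg = 0, habenular_period_deg = 0,
    speck_count = 0, noise_sd = 0, seed = 7))
})

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# voxelized solid sphere mask of radius r_vox (centre between voxels)
sphere_mask <- function(r_vox, voxel_size_um = 1) {
  n <- as.integer(2 * r_vox + 4)
  ctr <- (n + 1) / 2
  ax <- (seq_len(n) - ctr)^2
  v <- array(outer(outer(ax, ax, "+"), ax, "+") <= r_vox^2, c(n, n, n))
  binary_mask(v, voxel_size_um)
}

# flat slab mask with optional through-pores (cylinders along z)
slab_mask <- function(nx = 60, ny = 60, nz = 20, z0 = 8, z1 = 13,
                      pores = NULL, voxel_size_um = 1) {
  v <- array(FALSE, c(nx, ny, nz))
  v[3:(nx - 2), 3:(ny - 2), z0:z1] <- TRUE
  if (!is.null(pores)) {
    ii <- expand.grid(x = seq_len(nx), y = seq_len(ny))
    for (p in seq_len(nrow(pores))) {
      hit <- (ii$x - pores$x[p])^2 + (ii$y - pores$y[p])^2 <= pores$r[p]^2
      for (k in z0:z1) {
        pg <- v[, , k]
        pg[cbind(ii$x[hit], ii$y[hit])] <- FALSE
        v[, , k] <- pg
      }
    }
  }
  binary_mask(v, voxel_size_um)
}
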