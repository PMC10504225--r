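# Synthetic conical-spiral lamina phantom with exhaustively known
# ground truth. The lamina is a two-plate ribbon swept along a conical
# spiral: radius Archimedean in angle, axial position linear in angle
# (constant pitch). The radial width tapers linearly from the base to
# the apex value; the plate assembly (vestibular plate, gap, tympanic
# plate) has constant thickness. Through-plate cylindrical pores are
# placed by rejection sampling until each plate's voxel-counted pore
# fraction is within 1 percentage point of target; sparse bony pillars
# span the inter-plate gap; habenular openings are cylindrical bites on
# the lateral edge. Openings (pores and habenular bites) count toward
# pore space: the pore-free envelope is the full ribbon as constructed.

#' Phantom configuration
#'
#' Defaults model the adult human osseous spiral lamina: a sweep of
#' 990° (two and three-quarter turns), radial width tapering 1800 µm at
#' the base to 200 µm at the apex, and a 100 µm plate assembly (two
#' 25 µm plates around a 50 µm gap).
#'
#' @param voxel_size_um Isotropic voxel size (µm).
#' @param turns_deg Total angular extent of the sweep (degrees).
#' @param width_base_um,width_apex_um Radial width at theta = 0 and at
#'   `turns_deg`; the taper is linear in angle.
#' @param plate_thickness_um Single-plate thickness.
#' @param gap_um Inter-plate gap; assembly thickness is
#'   `2 * plate_thickness_um + gap_um`.
#' @param r_inner_base_um,r_inner_apex_um Modiolar (inner) wall radius
#'   at base and apex; linear in angle.
#' @param pitch_um_per_turn Axial drift of the mid-surface per 360°.
#' @param pore_fraction_vp,pore_fraction_tp Target pore fraction of
#'   each plate, in \[0, 1).
#' @param pore_radius_um_range Min/max pore cylinder radius (µm).
#' @param pore_radial_bias `"uniform"` (pore volume density uniform
#'   across the radial span) or `"middle-heavy"` (Beta(3,3)-distributed
#'   radial positions).
#' @param pore_edge_bleed If `TRUE`, uniform-bias pore centres may
#'   overhang the plate edges, giving strictly uniform coverage out to
#'   the rim (at the cost of rim scallops no shape-following envelope
#'   can restore). The default keeps centres half a radius inside the
#'   edges, as in the real plates where the rim is perforated only by
#'   the habenular openings.
#' @param pillar_density_per_deg Expected number of gap-spanning bony
#'   pillars per degree of sweep.
#' @param pillar_radius_um Pillar cylinder radius.
#' @param habenular_period_deg Angular period of habenular openings on
#'   the lateral edge (0 disables them).
#' @param habenular_notch_um Diameter of the cylindrical habenular bite
#'   centred on the lateral edge.
#' @param region_bounds_deg Angular cuts separating basal/middle/apex.
#' @param bone_gray,tissue_gray Gray levels (16-bit digital numbers).
#' @param noise_sd Additive Gaussian noise SD.
#' @param speck_count Number of small bright speck artifacts.
#' @param margin_vox Background margin around the geometry, in voxels.
#' @param seed Integer seed; all stochastic draws flow from it.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(voxel_size_um = 10,
                           turns_deg = 990,
                           width_base_um = 1800,
                           width_apex_um = 200,
                           plate_thickness_um = 25,
                           gap_um = 50,
                           r_inner_base_um = 300,
                           r_inner_apex_um = 150,
                           pitch_um_per_turn = 600,
                           pore_fraction_vp = 0.55,
                           pore_fraction_tp = 0.65,
                           pore_radius_um_range = c(12, 24),
                           pore_radial_bias = c("uniform", "middle-heavy"),
                           pore_edge_bleed = FALSE,
                           pillar_density_per_deg = 0.02,
                           pillar_radius_um = 20,
                           habenular_period_deg = 20,
                           habenular_notch_um = 50,
                           region_bounds_deg = c(360, 630),
                           bone_gray = 200,
                           tissue_gray = 50,
                           noise_sd = 10,
                           speck_count = 20,
                           margin_vox = 6,
                           seed = 1L) {
  cfg <- list(voxel_size_um = voxel_size_um, turns_deg = turns_deg,
              width_base_um = width_base_um, width_apex_um = width_apex_um,
              plate_thickness_um = plate_thickness_um, gap_um = gap_um,
              r_inner_base_um = r_inner_base_um,
              r_inner_apex_um = r_inner_apex_um,
              pitch_um_per_turn = pitch_um_per_turn,
              pore_fraction_vp = pore_fraction_vp,
              pore_fraction_tp = pore_fraction_tp,
              pore_radius_um_range = pore_radius_um_range,
              pore_radial_bias = match.arg(pore_radial_bias),
              pore_edge_bleed = isTRUE(pore_edge_bleed),
              pillar_density_per_deg = pillar_density_per_deg,
              pillar_radius_um = pillar_radius_um,
              habenular_period_deg = habenular_period_deg,
              habenular_notch_um = habenular_notch_um,
              region_bounds_deg = region_bounds_deg,
              bone_gray = bone_gray, tissue_gray = tissue_gray,
              noise_sd = noise_sd, speck_count = speck_count,
              margin_vox = margin_vox, seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  vox <- cfg$voxel_size_um
  if (!is.numeric(vox) || vox <= 0) stop("voxel_size_um must be positive")
  need2 <- function(value, name) {
    if (value < 2 * vox)
      stop(sprintf(
        "%s (%g um) is smaller than 2 voxels (%g um): geometry does not fit the lattice",
        name, value, 2 * vox))
  }
  if (cfg$turns_deg <= 0) stop("turns_deg must be positive")
  if (cfg$width_apex_um > cfg$width_base_um)
    stop("width_apex_um must not exceed width_base_um")
  need2(cfg$width_apex_um, "width_apex_um")
  need2(cfg$plate_thickness_um, "plate_thickness_um")
  need2(cfg$gap_um, "gap_um")
  if (cfg$r_inner_apex_um <= 0) stop("r_inner_apex_um must be positive")
  assembly <- 2 * cfg$plate_thickness_um + cfg$gap_um
  if (cfg$pitch_um_per_turn < assembly + 2 * vox)
    stop(sprintf(
      "pitch_um_per_turn (%g um) leaves less than 2 voxels of clearance between turns (assembly %g um)",
      cfg$pitch_um_per_turn, assembly))
  pf <- c(cfg$pore_fraction_vp, cfg$pore_fraction_tp)
  if (any(pf < 0) || any(pf >= 1))
    stop("pore fractions must lie in [0, 1)")
  rr <- cfg$pore_radius_um_range
  if (length(rr) != 2 || rr[1] > rr[2]) stop("bad pore_radius_um_range")
  if (any(pf > 0)) {
    need2(2 * rr[1], "pore diameter (2 * min pore radius)")
    if (rr[2] >= cfg$width_apex_um)
      stop("max pore radius must be smaller than the apex plate width")
  }
  if (cfg$pillar_density_per_deg < 0) stop("pillar density must be >= 0")
  if (cfg$pillar_density_per_deg > 0)
    need2(2 * cfg$pillar_radius_um, "pillar diameter")
  if (cfg$habenular_period_deg < 0) stop("habenular period must be >= 0")
  if (cfg$habenular_period_deg > 0)
    need2(cfg$habenular_notch_um, "habenular_notch_um")
  invisible(cfg)
}

# linear taper helpers
ph_r_inner <- function(cfg, th)
  cfg$r_inner_base_um +
    (cfg$r_inner_apex_um - cfg$r_inner_base_um) * th / cfg$turns_deg
ph_width <- function(cfg, th)
  cfg$width_base_um +
    (cfg$width_apex_um - cfg$width_base_um) * th / cfg$turns_deg

# carve material (set labels to 0) inside a z-bounded cylinder,
# restricted to `targets` labels; returns counts removed per label 1/2
carve_cylinder <- function(lab, geom, px, py, r_um, z_lo, z_hi, targets) {
  vox <- geom$vox
  ix1 <- max(1L, floor((px - r_um) / vox) + 1L)
  ix2 <- min(geom$nx, ceiling((px + r_um) / vox) + 1L)
  iy1 <- max(1L, floor((py - r_um) / vox) + 1L)
  iy2 <- min(geom$ny, ceiling((py + r_um) / vox) + 1L)
  iz1 <- max(1L, floor(z_lo / vox) + 1L)
  iz2 <- min(geom$nz, ceiling(z_hi / vox) + 1L)
  if (ix1 > ix2 || iy1 > iy2 || iz1 > iz2)
    return(list(lab = lab, removed = c(0L, 0L)))
  ix <- ix1:ix2
  iy <- iy1:iy2
  iz <- iz1:iz2
  dx <- (ix - 1) * vox - px
  dy <- (iy - 1) * vox - py
  disk <- outer(dx^2, dy^2, "+") <= r_um^2
  if (!any(disk)) return(list(lab = lab, removed = c(0L, 0L)))
  sub <- lab[ix, iy, iz, drop = FALSE]
  hit <- array(disk, dim(sub)) & array(sub %in% targets, dim(sub))
  removed <- c(sum(sub[hit] == 1L), sum(sub[hit] == 2L))
  sub[hit] <- 0L
  lab[ix, iy, iz] <- sub
  list(lab = lab, removed = removed)
}

#' Generate a spiral-lamina phantom
#'
#' Builds the voxelized two-plate conical-spiral lamina described by
#' `config`, carves habenular openings and through-plate pores, adds
#' inter-plate pillars, and renders a noisy grayscale volume with
#' speck artifacts. Deterministic for a fixed seed.
#'
#' @param config A `phantom_config`.
#' @return List with `volume` (a `gray_volume`) and `truth` (class
#'   `phantom_truth`): per-voxel material labels (0 none, 1 VP, 2 TP,
#'   3 pillar), the pore-free envelope labels, region labels, the
#'   construction `spiral_frame`, per plate x region porosity by voxel
#'   counting, the true width/thickness profiles, and the speck
#'   positions.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(cfg$seed)

  vox <- cfg$voxel_size_um
  t_um <- cfg$plate_thickness_um
  gap <- cfg$gap_um
  assembly <- 2 * t_um + gap
  margin <- cfg$margin_vox * vox
  r_out_max <- cfg$r_inner_base_um + cfg$width_base_um
  half <- ceiling((r_out_max + margin) / vox)
  nx <- ny <- 2L * half + 1L
  cxy <- half * vox  # spiral axis at the centre voxel
  z0 <- margin + assembly / 2
  z_top <- z0 + cfg$pitch_um_per_turn * cfg$turns_deg / 360 + assembly / 2
  nz <- as.integer(ceiling((z_top + margin) / vox)) + 1L
  geom <- list(vox = vox, nx = nx, ny = ny, nz = nz)

  # per-column geometry (independent of z)
  dx <- (seq_len(nx) - 1) * vox - cxy
  dy <- (seq_len(ny) - 1) * vox - cxy
  rho <- sqrt(outer(dx^2, dy^2, "+"))
  phi <- (atan2(rep(dy, each = nx), rep(dx, ny)) * 180 / pi) %% 360
  dim(phi) <- c(nx, ny)

  b <- cfg$region_bounds_deg
  turns <- cfg$turns_deg
  turn_data <- list()
  for (kt in 0:floor(turns / 360)) {
    th <- phi + 360 * kt
    ok <- th <= turns
    if (!any(ok)) next
    rin <- ph_r_inner(cfg, th)
    w <- ph_width(cfg, th)
    inplate <- ok & rho >= rin & rho <= rin + w
    if (!any(inplate)) next
    turn_data[[length(turn_data) + 1L]] <- list(
      sel = which(inplate),
      zc = (z0 + cfg$pitch_um_per_turn * th / 360)[inplate],
      reg = (1L + (th >= b[1]) + (th >= b[2]))[inplate])
  }

  lab <- array(0L, c(nx, ny, nz))
  region <- array(0L, c(nx, ny, nz))
  turn <- array(0L, c(nx, ny, nz))  # 1-based turn index of each voxel
  nxy <- as.double(nx) * ny
  for (k in seq_len(nz)) {
    pz <- (k - 1) * vox
    base <- (k - 1) * nxy
    for (ti in seq_along(turn_data)) {
      td <- turn_data[[ti]]
      vp <- pz >= td$zc + gap / 2 & pz < td$zc + gap / 2 + t_um
      tp <- pz <= td$zc - gap / 2 & pz > td$zc - gap / 2 - t_um
      if (any(vp)) {
        lab[base + td$sel[vp]] <- 1L
        region[base + td$sel[vp]] <- td$reg[vp]
        turn[base + td$sel[vp]] <- ti
      }
      if (any(tp)) {
        lab[base + td$sel[tp]] <- 2L
        region[base + td$sel[tp]] <- td$reg[tp]
        turn[base + td$sel[tp]] <- ti
      }
    }
  }

  envelope <- lab  # pore-free plate solids as constructed
  env_n <- c(sum(envelope == 1L), sum(envelope == 2L))
  removed <- c(0L, 0L)

  zc_of <- function(th) z0 + cfg$pitch_um_per_turn * th / 360
  xy_of <- function(th, radius) {
    a <- (th %% 360) * pi / 180
    c(cxy + radius * cos(a), cxy + radius * sin(a))
  }

  # habenular openings: cylindrical perforations tangent to the
  # lateral edge from inside (the openings sit at the rim where the
  # plates join, but leave the rim line itself largely intact)
  notches <- numeric(0)
  if (cfg$habenular_period_deg > 0) {
    notches <- seq(cfg$habenular_period_deg / 2, turns,
                   by = cfg$habenular_period_deg)
    for (thn in notches) {
      r_edge <- ph_r_inner(cfg, thn) + ph_width(cfg, thn) -
        cfg$habenular_notch_um / 2
      p <- xy_of(thn, r_edge)
      zc <- zc_of(thn)
      res <- carve_cylinder(lab, geom, p[1], p[2], cfg$habenular_notch_um / 2,
                            zc - assembly, zc + assembly, c(1L, 2L))
      lab <- res$lab
      removed <- removed + res$removed
    }
  }

  # Through-plate pores. Centres sit on a jittered hexagonal lattice in
  # the plate plane: unlike Poisson placement, which percolates into
  # wide unclosable lakes at the observed pore fractions, this keeps
  # pores as bounded windows separated by bone strands (the real plates
  # are lace-like). Sites are carved in random order with live voxel
  # counting until the plate's pore fraction is within the target band;
  # if the lattice is exhausted, small pores are added by rejection
  # sampling. "middle-heavy" bias thins lattice sites by 4u(1-u) of
  # the local radial fraction u.
  rr <- cfg$pore_radius_um_range
  mean_r2 <- (rr[1]^2 + rr[1] * rr[2] + rr[2]^2) / 3
  th_cdf_grid <- seq(0, turns, length.out = 2048)
  rin_g <- ph_r_inner(cfg, th_cdf_grid)
  rout_g <- rin_g + ph_width(cfg, th_cdf_grid)
  wgt <- rout_g^2 - rin_g^2
  th_cdf <- cumsum(wgt) / sum(wgt)
  sample_theta <- function() {
    u <- runif(1)
    th_cdf_grid[findInterval(u, th_cdf) + 1L]
  }
  middle_heavy <- cfg$pore_radial_bias == "middle-heavy"
  pore_log <- list(vp = 0L, tp = 0L)
  for (plate in 1:2) {
    target <- if (plate == 1) cfg$pore_fraction_vp else cfg$pore_fraction_tp
    if (target <= 0 || env_n[plate] == 0) next
    accept_mean <- if (middle_heavy) 2 / 3 else 1
    # hexagonal cell area sqrt(3)/2 * pitch^2; aim slightly above the
    # target so the shuffled carve loop can stop at the band
    pitch <- sqrt(2 * pi * mean_r2 * accept_mean /
                    (sqrt(3) * min(target, 0.85) * 1.1))
    # lattice sites per turn, in global plate-plane coordinates
    sites <- list()
    for (kt in 0:floor(turns / 360)) {
      th_lo <- 360 * kt
      if (th_lo > turns) break
      th_hi <- min(360 * (kt + 1), turns)
      ro <- max(ph_r_inner(cfg, th_lo) + ph_width(cfg, th_lo),
                ph_r_inner(cfg, th_hi) + ph_width(cfg, th_hi)) + rr[2]
      gy <- seq(cxy - ro, cxy + ro, by = pitch * sqrt(3) / 2)
      g <- do.call(rbind, lapply(seq_along(gy), function(ri) {
        xo <- if (ri %% 2 == 0) pitch / 2 else 0
        data.frame(x = seq(cxy - ro + xo, cxy + ro, by = pitch), y = gy[ri])
      }))
      g$x <- g$x + runif(nrow(g), -0.04, 0.04) * pitch
      g$y <- g$y + runif(nrow(g), -0.04, 0.04) * pitch
      s <- sqrt((g$x - cxy)^2 + (g$y - cxy)^2)
      phig <- (atan2(g$y - cxy, g$x - cxy) * 180 / pi) %% 360
      thg <- phig + 360 * kt
      ok <- thg <= turns
      rin <- ph_r_inner(cfg, thg)
      w <- ph_width(cfg, thg)
      ok <- if (!middle_heavy && cfg$pore_edge_bleed)
        ok & s >= rin - rr[2] & s <= rin + w + rr[2]
      else ok & s >= rin + 0.5 * rr[1] & s <= rin + w - 0.5 * rr[1]
      if (middle_heavy) {
        u <- pmin(pmax((s - rin) / w, 0), 1)
        ok <- ok & runif(length(u)) < 4 * u * (1 - u)
      }
      if (any(ok))
        sites[[length(sites) + 1L]] <- data.frame(
          x = g$x[ok], y = g$y[ok], theta = thg[ok])
    }
    sites <- do.call(rbind, sites)
    sites <- sites[sample.int(nrow(sites)), , drop = FALSE]
    npores <- 0L
    i <- 1L
    while (removed[plate] / env_n[plate] < target - 0.002 &&
           i <= nrow(sites)) {
      r_p <- runif(1, rr[1], rr[2])
      zc <- zc_of(sites$theta[i])
      res <- carve_cylinder(lab, geom, sites$x[i], sites$y[i], r_p,
                            zc - assembly, zc + assembly, plate)
      lab <- res$lab
      if (res$removed[plate] > 0) npores <- npores + 1L
      removed <- removed + res$removed
      i <- i + 1L
    }
    # top-up with small pores if the lattice was exhausted
    attempts <- 0L
    while (removed[plate] / env_n[plate] < target - 0.002 &&
           attempts < 20000L) {
      attempts <- attempts + 1L
      thp <- sample_theta()
      rin <- ph_r_inner(cfg, thp)
      w <- ph_width(cfg, thp)
      s <- if (middle_heavy) rin + w * rbeta(1, 3, 3)
      else if (cfg$pore_edge_bleed) {
        s1 <- max(rin - rr[1], 1)
        sqrt(runif(1, s1^2, (rin + w + rr[1])^2))
      } else {
        s1 <- rin + 0.5 * rr[1]
        sqrt(runif(1, s1^2, (rin + w - 0.5 * rr[1])^2))
      }
      p <- xy_of(thp, s)
      zc <- zc_of(thp)
      res <- carve_cylinder(lab, geom, p[1], p[2], rr[1],
                            zc - assembly, zc + assembly, plate)
      lab <- res$lab
      if (res$removed[plate] > 0) npores <- npores + 1L
      removed <- removed + res$removed
    }
    pore_log[[plate]] <- npores
  }

  # bony pillars spanning the inter-plate gap
  pillars <- data.frame()
  n_pil <- if (cfg$pillar_density_per_deg > 0)
    rpois(1, cfg$pillar_density_per_deg * turns) else 0L
  if (n_pil > 0) {
    thp <- runif(n_pil, 0, turns)
    u <- runif(n_pil, 0.15, 0.85)
    for (i in seq_len(n_pil)) {
      rin <- ph_r_inner(cfg, thp[i])
      w <- ph_width(cfg, thp[i])
      s <- rin + u[i] * w
      p <- xy_of(thp[i], s)
      zc <- zc_of(thp[i])
      r_um <- cfg$pillar_radius_um
      ix <- max(1L, floor((p[1] - r_um) / vox) + 1L):
        min(nx, ceiling((p[1] + r_um) / vox) + 1L)
      iy <- max(1L, floor((p[2] - r_um) / vox) + 1L):
        min(ny, ceiling((p[2] + r_um) / vox) + 1L)
      iz <- max(1L, floor((zc - gap / 2) / vox) + 1L):
        min(nz, ceiling((zc + gap / 2) / vox) + 1L)
      ddx <- (ix - 1) * vox - p[1]
      ddy <- (iy - 1) * vox - p[2]
      disk <- outer(ddx^2, ddy^2, "+") <= r_um^2
      sub <- lab[ix, iy, iz, drop = FALSE]
      rsub <- region[ix, iy, iz, drop = FALSE]
      fill <- array(disk, dim(sub)) & sub == 0L
      # restrict to axial positions inside the gap
      pzv <- (iz - 1) * vox
      ingap <- pzv >= zc - gap / 2 & pzv <= zc + gap / 2
      fill <- fill & rep(ingap, each = length(ix) * length(iy))
      sub[fill] <- 3L
      regv <- 1L + (thp[i] >= b[1]) + (thp[i] >= b[2])
      rsub[fill] <- regv
      tsub <- turn[ix, iy, iz, drop = FALSE]
      tsub[fill] <- as.integer(thp[i] %/% 360) + 1L
      lab[ix, iy, iz] <- sub
      region[ix, iy, iz] <- rsub
      turn[ix, iy, iz] <- tsub
      pillars <- rbind(pillars, data.frame(theta_deg = thp[i],
                                           radius_frac = u[i]))
    }
  }

  # grayscale rendering with noise and speck artifacts
  gray <- array(cfg$tissue_gray, c(nx, ny, nz))
  gray[lab > 0L] <- cfg$bone_gray
  if (cfg$noise_sd > 0)
    gray <- gray + rnorm(length(gray), 0, cfg$noise_sd)
  specks <- integer(0)
  if (cfg$speck_count > 0) {
    placed <- 0L
    tries <- 0L
    while (placed < cfg$speck_count && tries < 100L * cfg$speck_count) {
      tries <- tries + 1L
      ci <- sample(4:(nx - 3), 1)
      cj <- sample(4:(ny - 3), 1)
      ck <- sample(4:(nz - 3), 1)
      # keep specks clear of the lamina so they are true artifacts
      if (any(lab[(ci - 3):(ci + 3), (cj - 3):(cj + 3),
                  (ck - 3):(ck + 3)] > 0L)) next
      rs <- sample(1:2, 1)
      box <- as.matrix(expand.grid((ci - rs):(ci + rs), (cj - rs):(cj + rs),
                                   (ck - rs):(ck + rs)))
      keep <- rowSums(sweep(box, 2, c(ci, cj, ck))^2) <= rs^2
      box <- box[keep, , drop = FALSE]
      lin <- box[, 1] + (box[, 2] - 1) * nx + (box[, 3] - 1) * nx * ny
      gray[lin] <- cfg$bone_gray + rnorm(length(lin), 0, cfg$noise_sd)
      specks <- c(specks, as.integer(lin))
      placed <- placed + 1L
    }
  }

  # construction frame: helicotrema centre at the top of the material
  kmax <- max(which(apply(lab > 0L, 3, any)))
  z_top_mat <- (kmax - 1) * vox
  frame <- spiral_frame(center_um = c(cxy, cxy, z_top_mat),
                        axis_unit = c(0, 0, 1),
                        zero_angle_unit = c(1, 0, 0), handedness = 1,
                        pitch_um_per_turn = cfg$pitch_um_per_turn,
                        base_offset_um = z0 - z_top_mat)

  # per plate x region porosity by voxel counting
  code_env <- envelope * 4L + region
  code_mat <- lab * 4L + region
  te <- tabulate(code_env + 1L, nbins = 17L)
  tm <- tabulate(code_mat + 1L, nbins = 17L)
  rows <- expand.grid(region = c("basal", "middle", "apex"),
                      plate = c("vp", "tp"), stringsAsFactors = FALSE)
  rows$n_envelope <- mapply(function(p, r)
    te[(match(p, c("vp", "tp"))) * 4L + r + 1L],
    rows$plate, match(rows$region, c("basal", "middle", "apex")))
  rows$n_material <- mapply(function(p, r)
    tm[(match(p, c("vp", "tp"))) * 4L + r + 1L],
    rows$plate, match(rows$region, c("basal", "middle", "apex")))
  rows$porosity_percent <- ifelse(rows$n_envelope > 0,
                                  100 * (rows$n_envelope - rows$n_material) /
                                    rows$n_envelope, NA_real_)
  rows <- rows[, c("plate", "region", "n_envelope", "n_material",
                   "porosity_percent")]

  th_grid <- seq(0, turns, by = 1)
  profile_true <- data.frame(theta_deg = th_grid,
                             width_um = ph_width(cfg, th_grid),
                             thickness_um = assembly)

  truth <- structure(list(
    label = lab, envelope = envelope, region = region, turn = turn,
    frame = frame,
    config = cfg, true_porosity = rows, profile_true = profile_true,
    assembly_thickness_um = assembly, specks = specks,
    pillars = pillars, pore_count = pore_log,
    notch_angles_deg = notches), class = "phantom_truth")

  vol <- gray_volume(gray, vox)
  list(volume = vol, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  d <- dim(x$label)
  cat(sprintf("<phantom_truth> %d x %d x %d voxels @ %g um, %s sweep %g deg\n",
              d[1], d[2], d[3], x$config$voxel_size_um,
              "conical spiral,", x$config$turns_deg))
  print(x$true_porosity, digits = 3)
  invisible(x)
}

#' Material mask of a phantom (all labels)
#' @param truth A `phantom_truth`.
#' @return A `binary_mask`.
#' @export
phantom_material_mask <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  binary_mask(truth$label > 0L, truth$config$voxel_size_um,
              provenance = list(source = "phantom ground truth"))
}

#' Ground-truth plate mask of a phantom
#' @param truth A `phantom_truth`.
#' @param plate `"vp"`, `"tp"`, or `"pillar"`.
#' @param envelope If `TRUE`, return the pore-free envelope instead of
#'   the porous material.
#' @return A `binary_mask`.
#' @export
phantom_plate_mask <- function(truth, plate = c("vp", "tp", "pillar"),
                               envelope = FALSE) {
  stopifnot(inherits(truth, "phantom_truth"))
  plate <- match.arg(plate)
  code <- match(plate, c("vp", "tp", "pillar"))
  src <- if (envelope) truth$envelope else truth$label
  binary_mask(src == code, truth$config$voxel_size_um,
              provenance = list(source = "phantom ground truth",
                                plate = plate, envelope = envelope))
}

#' Ground-truth region partition of a phantom
#' @param truth A `phantom_truth`.
#' @return A `region_partition` on the construction angles.
#' @export
phantom_region_partition <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  structure(list(labels = truth$region,
                 angle_bounds_deg = truth$config$region_bounds_deg,
                 region_names = c("basal", "middle", "apex"),
                 voxel_size_um = truth$config$voxel_size_um,
                 origin = c(0, 0, 0)),
            class = "region_partition")
}

#' Ground-truth porosity by voxel counting
#'
#' The brute-force oracle for the filled-envelope porosity statistic:
#' `100 * (N_envelope - N_material) / N_envelope`, with counts
#' restricted to the requested plate and region. This is the reference
#' against which the mesh-based pipeline porosity is judged.
#'
#' @param truth A `phantom_truth`.
#' @param plate `"vp"` or `"tp"`.
#' @param region `"basal"`, `"middle"`, `"apex"`, or `"all"`.
#' @return Porosity in percent.
#' @export
oracle_porosity <- function(truth, plate = c("vp", "tp"),
                            region = c("all", "basal", "middle", "apex")) {
  stopifnot(inherits(truth, "phantom_truth"))
  plate <- match.arg(plate)
  region <- match.arg(region)
  pc <- match(plate, c("vp", "tp"))
  esel <- truth$envelope == pc
  if (region != "all") {
    rc <- match(region, c("basal", "middle", "apex"))
    esel <- esel & truth$region == rc
  }
  n_env <- sum(esel)
  if (n_env == 0)
    stop(sprintf("empty envelope selection for plate %s, region %s",
                 plate, region))
  n_mat <- sum(truth$label[esel] == pc)
  100 * (n_env - n_mat) / n_env
}
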