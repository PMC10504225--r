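# Spiral anatomical coordinate system. The frame is anchored at the
# helicotrema (apical centre), with the cochlear central axis as z-like
# direction and an in-plane reference ray fixing theta = 0 at the basal
# start of the structure. The angular coordinate is unwrapped across
# turns using the axial drift per turn (the pitch).

#' Spiral measurement frame
#'
#' @param center_um Helicotrema point (3-vector, µm).
#' @param axis_unit Central axis direction (3-vector; normalised).
#' @param zero_angle_unit In-plane direction fixing theta = 0
#'   (orthogonalised against the axis and normalised).
#' @param handedness +1 if theta increases counter-clockwise about
#'   `axis_unit` (right-hand rule), -1 otherwise.
#' @param pitch_um_per_turn Axial drift of the spiral mid-surface per
#'   360° turn (µm); needed to unwrap angles across turns. May be `NULL`
#'   for single-turn structures (see [estimate_pitch()]).
#' @param base_offset_um Axial offset (relative to `center_um`, along
#'   `axis_unit`) of the spiral mid-surface at theta = 0.
#' @return An object of class `spiral_frame`.
#' @export
spiral_frame <- function(center_um, axis_unit = c(0, 0, 1),
                         zero_angle_unit = c(1, 0, 0), handedness = 1,
                         pitch_um_per_turn = NULL, base_offset_um = NULL) {
  axis <- axis_unit / sqrt(sum(axis_unit^2))
  z0 <- zero_angle_unit - sum(zero_angle_unit * axis) * axis
  nz <- sqrt(sum(z0^2))
  if (nz < 1e-8)
    stop("zero_angle_unit is parallel to the axis")
  z0 <- z0 / nz
  if (!handedness %in% c(-1, 1)) stop("handedness must be +1 or -1")
  structure(list(center_um = as.numeric(center_um), axis_unit = axis,
                 zero_angle_unit = z0, handedness = handedness,
                 pitch_um_per_turn = pitch_um_per_turn,
                 base_offset_um = base_offset_um),
            class = "spiral_frame")
}

#' @export
print.spiral_frame <- function(x, ...) {
  cat(sprintf("<spiral_frame> center (%.1f, %.1f, %.1f) um, handedness %+d\n",
              x$center_um[1], x$center_um[2], x$center_um[3], x$handedness))
  cat(sprintf("  axis (%.3f, %.3f, %.3f), zero-angle (%.3f, %.3f, %.3f)\n",
              x$axis_unit[1], x$axis_unit[2], x$axis_unit[3],
              x$zero_angle_unit[1], x$zero_angle_unit[2],
              x$zero_angle_unit[3]))
  if (!is.null(x$pitch_um_per_turn))
    cat(sprintf("  pitch %.1f um/turn, base offset %.1f um\n",
                x$pitch_um_per_turn,
                if (is.null(x$base_offset_um)) NA_real_ else x$base_offset_um))
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# cylindrical coordinates of points (n x 3 physical µm) in a frame:
# radial distance rho, azimuth phi in [0, 360), axial coordinate ax
frame_cylindrical <- function(points_um, frame) {
  points_um <- matrix(points_um, ncol = 3)
  v <- sweep(points_um, 2, frame$center_um)
  e1 <- frame$zero_angle_unit
  e2 <- frame$handedness * cross3(frame$axis_unit, e1)
  x <- v %*% e1
  y <- v %*% e2
  ax <- v %*% frame$axis_unit
  phi <- (atan2(y, x) * 180 / pi) %% 360
  list(rho = sqrt(x^2 + y^2)[, 1], phi = phi[, 1], ax = ax[, 1])
}

#' Unwrapped angular coordinate of points
#'
#' Returns the spiral angle theta in degrees, accumulated across turns:
#' the in-plane azimuth relative to the zero-angle ray, with the turn
#' index resolved from the axial coordinate via the frame's pitch. For
#' frames without a pitch the structure is treated as a single turn
#' (theta = azimuth).
#'
#' @param point_um Point(s) in µm: a 3-vector or an n x 3 matrix.
#' @param frame A `spiral_frame`.
#' @return Numeric vector of angles in degrees.
#' @export
angular_coordinate <- function(point_um, frame) {
  stopifnot(inherits(frame, "spiral_frame"))
  cyl <- frame_cylindrical(point_um, frame)
  if (any(cyl$rho < 1e-9))
    stop("point lies on the spiral axis; the angle is undefined")
  if (is.null(frame$pitch_um_per_turn)) return(cyl$phi)
  pitch <- frame$pitch_um_per_turn
  s0 <- if (is.null(frame$base_offset_um)) 0 else frame$base_offset_um
  s <- cyl$ax - pitch * cyl$phi / 360
  k <- round((s - s0) / pitch)
  cyl$phi + 360 * k
}

# rho/phi/ax/theta for every TRUE voxel of a mask (used by all
# angle-indexed measurements); idx rows match which(mask, arr.ind=TRUE)
spiral_coords <- function(mask, frame) {
  idx <- mask_indices(mask)
  pts <- voxel_centers_um(idx, mask$voxel_size_um, mask$origin)
  cyl <- frame_cylindrical(pts, frame)
  theta <- if (is.null(frame$pitch_um_per_turn)) cyl$phi else {
    pitch <- frame$pitch_um_per_turn
    s0 <- if (is.null(frame$base_offset_um)) 0 else frame$base_offset_um
    s <- cyl$ax - pitch * cyl$phi / 360
    cyl$phi + 360 * round((s - s0) / pitch)
  }
  list(idx = idx, rho = cyl$rho, phi = cyl$phi, ax = cyl$ax, theta = theta)
}

#' Estimate the spiral pitch and base offset from a mask
#'
#' Clusters the axial positions of material within azimuthal bins; the
#' median axial spacing between successive turn clusters is the pitch.
#' The base offset anchors theta = 0 at the basal-most turn of the
#' mask. Requires the mask to sweep more than one full turn.
#'
#' @param mask A `binary_mask`.
#' @param frame A `spiral_frame` (pitch fields may be empty).
#' @param bin_deg Azimuthal bin width in degrees.
#' @return The frame with `pitch_um_per_turn` and `base_offset_um` set.
#' @export
estimate_pitch <- function(mask, frame, bin_deg = 10) {
  stopifnot(inherits(mask, "binary_mask"), inherits(frame, "spiral_frame"))
  cyl <- frame_cylindrical(
    voxel_centers_um(mask_indices(mask), mask$voxel_size_um, mask$origin),
    frame)
  vox <- mask$voxel_size_um
  bins <- split(cyl$ax, floor(cyl$phi / bin_deg))
  deltas <- numeric(0)
  for (z in bins) {
    if (length(z) < 10) next
    z <- sort(z)
    gaps <- diff(z)
    if (!length(gaps) || max(gaps) < 4 * vox) next
    cut <- which(gaps > 0.5 * max(gaps) & gaps > 4 * vox)
    if (!length(cut)) next
    starts <- c(1, cut + 1)
    ends <- c(cut, length(z))
    centers <- (z[starts] + z[ends]) / 2
    if (length(centers) >= 2) deltas <- c(deltas, diff(centers))
  }
  if (!length(deltas))
    stop("could not identify successive turns; the mask must sweep more than one full turn (or supply the pitch explicitly)")
  pitch <- median(deltas)
  s <- sort(cyl$ax - pitch * cyl$phi / 360)
  gaps <- diff(s)
  cut <- which(gaps > pitch / 2)
  starts <- c(1L, cut + 1L)
  ends <- c(cut, length(s))
  sizes <- ends - starts + 1L
  # ignore stray-voxel clusters (residual artifacts) when anchoring
  keep <- sizes >= max(10, 0.005 * length(s))
  if (!any(keep)) keep <- sizes == max(sizes)
  first <- which(keep)[1]
  s0 <- mean(s[starts[first]:ends[first]])
  frame$pitch_um_per_turn <- pitch
  frame$base_offset_um <- s0
  frame
}

# Kåsa algebraic circle fit; returns c(cx, cy)
circle_fit <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  sol[1:2]
}

#' Fit a spiral measurement frame to a mask
#'
#' With landmarks (a list with `center` and `axis`, optionally
#' `zero_angle`, `handedness`, `pitch_um_per_turn`, `base_offset_um`)
#' they are normalised and passed through. Otherwise the axis is the
#' smallest-variance principal direction of the mask's second-moment
#' tensor, the in-plane centre is refined by fitting an Archimedean
#' spiral to the modiolar (inner) edge of the apical turn, and the
#' centre point is placed at the apical end of the mask (the
#' helicotrema). Handedness is inferred from the axial drift direction
#' of the sweep.
#'
#' @param mask A `binary_mask` sweeping more than 360°, or any mask if
#'   landmarks are supplied.
#' @param landmarks Optional list as described above.
#' @return A `spiral_frame`.
#' @export
fit_spiral_frame <- function(mask, landmarks = NULL) {
  if (!is.null(landmarks)) {
    return(spiral_frame(
      center_um = landmarks$center,
      axis_unit = landmarks$axis,
      zero_angle_unit = if (is.null(landmarks$zero_angle))
        default_zero_angle(landmarks$axis) else landmarks$zero_angle,
      handedness = if (is.null(landmarks$handedness)) 1
        else landmarks$handedness,
      pitch_um_per_turn = landmarks$pitch_um_per_turn,
      base_offset_um = landmarks$base_offset_um))
  }
  stopifnot(inherits(mask, "binary_mask"))
  vox <- mask$voxel_size_um
  pts <- voxel_centers_um(mask_indices(mask), vox, mask$origin)
  if (nrow(pts) < 100) stop("too few material voxels to fit a frame")
  ctr <- colMeans(pts)
  cv <- crossprod(sweep(pts, 2, ctr)) / nrow(pts)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- eg$values
  if (ev[3] / ev[1] > 0.5)
    stop("near-isotropic mask moments; frame is ambiguous - supply landmarks")
  axis <- eg$vectors[, 3]
  # Refine by averaging local sheet normals: the raw second-moment
  # axis leans when the tapering width makes the mass azimuthally
  # asymmetric, but the plate normal equals the central axis up to the
  # local pitch slope, whose azimuthal component cancels when
  # neighbourhoods are sampled evenly around the axis. Neighbourhoods
  # must comfortably exceed the plate-assembly thickness so the local
  # smallest principal direction is the sheet normal.
  for (it in 1:2) {
    bb <- eigen_basis_perp(axis)
    vv <- sweep(pts, 2, ctr)
    phi_d <- (atan2(vv %*% bb$e2, vv %*% bb$e1) * 180 / pi) %% 360
    rad <- max(12 * vox, 160)
    nsum <- c(0, 0, 0)
    for (b in seq(0, 355, by = 5)) {
      sel <- which(phi_d >= b & phi_d < b + 5)
      if (length(sel) < 30) next
      cen <- colMeans(pts[sel, , drop = FALSE])
      d2 <- rowSums(sweep(pts[sel, , drop = FALSE], 2, cen)^2)
      seed <- pts[sel[which.min(d2)], ]
      nb <- pts[abs(pts[, 1] - seed[1]) <= rad &
                  abs(pts[, 2] - seed[2]) <= rad &
                  abs(pts[, 3] - seed[3]) <= rad, , drop = FALSE]
      if (nrow(nb) < 40) next
      egl <- eigen(crossprod(sweep(nb, 2, colMeans(nb))), symmetric = TRUE)
      if (egl$values[3] > 0.3 * egl$values[2]) next  # not sheet-like here
      n_loc <- egl$vectors[, 3]
      if (sum(n_loc * axis) < 0) n_loc <- -n_loc
      nsum <- nsum + n_loc
    }
    if (sum(nsum^2) > 0) axis <- nsum / sqrt(sum(nsum^2))
  }
  bb <- eigen_basis_perp(axis)
  e1 <- bb$e1
  e2 <- bb$e2
  v <- sweep(pts, 2, ctr)
  px <- v %*% e1
  py <- v %*% e2
  ax <- (v %*% axis)[, 1]
  rho0 <- sqrt(px^2 + py^2)[, 1]
  phi0 <- (atan2(py, px) * 180 / pi) %% 360
  cover <- length(unique(floor(phi0 / 10)))
  if (cover < 33)
    stop("mask does not sweep a full turn about the candidate axis; supply landmarks")

  # orient the axis toward the apex (the narrower end of the cone)
  lo <- ax <= quantile(ax, 0.25)
  hi <- ax >= quantile(ax, 0.75)
  if (mean(rho0[lo]) < mean(rho0[hi])) {
    axis <- -axis
    e2 <- -e2  # keep (e1, e2, axis) right-handed
    ax <- -ax
    py <- -py
  }

  # inner (modiolar) edge of the apical band, one point per 5° azimuth
  band <- ax >= quantile(ax, 0.70)
  bx <- px[band]; by <- py[band]; bax <- ax[band]
  cen <- c(0, 0)
  for (iter in 1:3) {
    rx <- bx - cen[1]; ry <- by - cen[2]
    brho <- sqrt(rx^2 + ry^2)
    bphi <- (atan2(ry, rx) * 180 / pi) %% 360
    bb <- floor(bphi / 5)
    sel <- unlist(lapply(split(seq_along(bb), bb), function(i)
      i[which.min(brho[i])]), use.names = FALSE)
    ex <- bx[sel]; ey <- by[sel]; eax <- bax[sel]
    if (iter == 1) {
      cen <- circle_fit(ex, ey)
      next
    }
    # unwrap the edge angles by axial order and fit rho = a + b*theta
    obj <- function(cc) {
      rxx <- ex - cc[1]; ryy <- ey - cc[2]
      rr <- sqrt(rxx^2 + ryy^2)
      ph <- (atan2(ryy, rxx) * 180 / pi) %% 360
      ord <- order(eax)
      dph <- diff(ph[ord])
      dph <- ((dph + 180) %% 360) - 180
      th <- cumsum(c(ph[ord][1], dph))
      fit <- stats::lm.fit(cbind(1, th), rr[ord])
      sum(fit$residuals^2)
    }
    cen <- optim(cen, obj, method = "Nelder-Mead")$par
  }
  # degenerate-geometry guard about the refined centre: a planar or
  # non-spiral mask has material on (or arbitrarily near) the axis
  if (min(sqrt((px - cen[1])^2 + (py - cen[2])^2)) < 3 * vox)
    stop("material passes through the candidate axis (planar or non-spiral mask); supply landmarks")
  center <- ctr + cen[1] * e1 + cen[2] * e2 + max(ax) * axis

  # handedness: does the axial coordinate rise with counter-clockwise
  # azimuth about the axis (right-handed spiral toward the apex)?
  rx <- px - cen[1]; ry <- py - cen[2]
  phi <- (atan2(ry, rx) * 180 / pi) %% 360
  mz <- tapply(ax, floor(phi / 15), mean)
  slope <- stats::coef(stats::lm.fit(cbind(1, as.numeric(names(mz))),
                                     as.numeric(mz)))[2]
  handed <- if (slope >= 0) 1 else -1
  spiral_frame(center_um = center, axis_unit = axis,
               zero_angle_unit = e1, handedness = handed)
}

# any orthonormal in-plane basis perpendicular to a unit axis
eigen_basis_perp <- function(axis) {
  e1 <- default_zero_angle(axis)
  e1 <- e1 - sum(e1 * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  list(e1 = e1, e2 = cross3(axis, e1))
}

default_zero_angle <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  cand <- c(1, 0, 0)
  if (abs(sum(cand * axis)) > 0.9) cand <- c(0, 1, 0)
  cand
}

# 26-connected component labels of selected coordinate rows
components_sel <- function(idx) {
  lo <- apply(idx, 2, min)
  d <- apply(idx, 2, max) - lo + 1L
  sub <- array(FALSE, d)
  sub[cbind(idx[, 1] - lo[1] + 1L, idx[, 2] - lo[2] + 1L,
            idx[, 3] - lo[3] + 1L)] <- TRUE
  lab <- cpp_label_components(as.logical(sub), as.integer(d), 26L)
  array(lab, d)[cbind(idx[, 1] - lo[1] + 1L, idx[, 2] - lo[2] + 1L,
                      idx[, 3] - lo[3] + 1L)]
}

# The lamina cross-section in an angular slab fragments wherever pores
# cross it. Components whose radial intervals are separated by no more
# than `bridge_gap_um` are chained into one structure (a pore-scale
# gap is part of the lamina); the voxel-richest chain is the lamina,
# anything farther away (specks, the spiral ganglion) is not.
lamina_chain_sel <- function(idx, rho, bridge_gap_um) {
  comp <- components_sel(idx)
  rmin <- tapply(rho, comp, min)
  rmax <- tapply(rho, comp, max)
  n <- tapply(rho, comp, length)
  ord <- order(rmin)
  chain <- integer(length(ord))
  cur <- 1L
  cur_rmax <- rmax[ord[1]]
  chain[1] <- cur
  if (length(ord) > 1)
    for (i in 2:length(ord)) {
      if (rmin[ord[i]] <= cur_rmax + bridge_gap_um) {
        cur_rmax <- max(cur_rmax, rmax[ord[i]])
      } else {
        cur <- cur + 1L
        cur_rmax <- rmax[ord[i]]
      }
      chain[i] <- cur
    }
  chain_n <- tapply(n[ord], chain, sum)
  best <- as.integer(names(chain_n)[which.max(chain_n)])
  keep_comps <- as.integer(names(rmin)[ord[chain == best]])
  comp %in% keep_comps
}

# Shared slice selection for width/thickness at one angle. The
# angular half-width is never allowed to fall below one voxel of
# tangential extent, otherwise the slab would have radial gaps near
# the modiolus and the connected-component step would truncate it.
slice_at_angle <- function(coords, theta_deg, delta_deg, min_radius_um,
                           vox) {
  half <- pmax(delta_deg / 2, vox / pmax(coords$rho, vox) * 180 / pi)
  sel <- abs(coords$theta - theta_deg) <= half
  if (!is.null(min_radius_um)) sel <- sel & coords$rho >= min_radius_um
  which(sel)
}

width_thickness_at <- function(mask, coords, theta_deg, delta_deg,
                               min_radius_um, radial_fracs,
                               bridge_gap_um = NULL) {
  vox <- mask$voxel_size_um
  if (is.null(bridge_gap_um)) bridge_gap_um <- 8 * vox
  sel <- slice_at_angle(coords, theta_deg, delta_deg, min_radius_um, vox)
  out <- list(width = NA_real_,
              thickness = setNames(rep(NA_real_, length(radial_fracs)),
                                   names(radial_fracs)),
              defined = FALSE)
  if (!length(sel)) return(out)
  # radial span of the lamina chain (drops stray specks and other
  # distant structures); the two plates share the same span
  keep <- lamina_chain_sel(coords$idx[sel, , drop = FALSE],
                           coords$rho[sel], bridge_gap_um)
  rho_main <- coords$rho[sel][keep]
  rmin <- min(rho_main); rmax <- max(rho_main)
  out$width <- rmax - rmin + vox
  out$defined <- TRUE
  # thickness spans the whole assembly: measure over every slab voxel
  # in the radial column (the plates are separate components)
  rho <- coords$rho[sel]
  axv <- coords$ax[sel]
  inspan <- rho >= rmin - vox & rho <= rmax + vox
  for (nm in names(radial_fracs)) {
    rt <- rmin + radial_fracs[[nm]] * (rmax - rmin)
    col <- inspan & abs(rho - rt) <= 2 * vox
    if (!any(col)) col <- inspan & abs(rho - rt) <= 4 * vox  # widen once
    if (any(col))
      out$thickness[[nm]] <- max(axv[col]) - min(axv[col]) + vox
  }
  out
}

#' OSL width at a spiral angle
#'
#' Intersects the mask with the angular slab at `theta_deg` (voxels
#' whose unwrapped angle is within ±`delta_deg`/2, on the correct
#' turn), keeps the largest connected component, and returns the radial
#' extent from the modiolar (inner) wall to the lateral edge.
#'
#' @param mask A `binary_mask`.
#' @param frame A `spiral_frame` (with pitch for multi-turn masks).
#' @param theta_deg Target angle in degrees.
#' @param delta_deg Angular slab width (default 2°).
#' @param min_radius_um Optional inner-radius clip excluding the spiral
#'   ganglion region from the measurement.
#' @param bridge_gap_um Radial gaps up to this size are treated as
#'   pores within the lamina; larger gaps separate it from unrelated
#'   structures (default 8 voxels).
#' @return Width in µm.
#' @export
width_at_angle <- function(mask, frame, theta_deg, delta_deg = 2,
                           min_radius_um = NULL, bridge_gap_um = NULL) {
  coords <- spiral_coords(mask, frame)
  res <- width_thickness_at(mask, coords, theta_deg, delta_deg,
                            min_radius_um, list(), bridge_gap_um)
  if (!res$defined)
    stop(sprintf("no material intersects the angular slab at %.1f deg",
                 theta_deg))
  res$width
}

#' OSL thickness at a spiral angle and radial point
#'
#' Thickness is the transverse (axial) height of the plate assembly -
#' outer vestibular-plate surface to outer tympanic-plate surface -
#' within a narrow radial column at the chosen radial point. Radial
#' points map to fractions of the local radial span: lateral 0.9,
#' middle 0.5, medial 0.1. An empty column (a pore at the sample point)
#' is widened once from ±2 to ±4 voxels; if still empty the sample is
#' undefined.
#'
#' @inheritParams width_at_angle
#' @param radial_point One of `"lateral"`, `"middle"`, `"medial"`.
#' @return Thickness in µm.
#' @export
thickness_at <- function(mask, frame, theta_deg,
                         radial_point = c("lateral", "middle", "medial"),
                         delta_deg = 2, min_radius_um = NULL,
                         bridge_gap_um = NULL) {
  radial_point <- match.arg(radial_point)
  fr <- list(lateral = 0.9, middle = 0.5, medial = 0.1)[radial_point]
  coords <- spiral_coords(mask, frame)
  res <- width_thickness_at(mask, coords, theta_deg, delta_deg,
                            min_radius_um, fr, bridge_gap_um)
  if (!res$defined)
    stop(sprintf("no material intersects the angular slab at %.1f deg",
                 theta_deg))
  if (is.na(res$thickness[[radial_point]]))
    stop(sprintf("column at %.1f deg (%s) is empty even after widening",
                 theta_deg, radial_point))
  res$thickness[[radial_point]]
}

#' Width/thickness profile along the spiral
#'
#' Samples width and thickness (at the lateral, middle, and medial
#' radial points) at theta = 0, `step_deg`, 2·`step_deg`, ... and
#' summarises mean and SD per region. The default 45° step reproduces
#' the four-dissection-plane scheme (two measurement azimuths per
#' plane); finer steps are allowed. Undefined samples are flagged and
#' excluded from the summaries, with counts reported.
#'
#' @inheritParams width_at_angle
#' @param step_deg Angular sampling step (default 45°).
#' @param regions Optional `region_partition`; its angle bounds assign
#'   samples to named regions. Without it a single region `"all"` is
#'   used.
#' @return An object of class `osl_profile` with elements `samples`
#'   (data frame: theta_deg, width_um, thickness at three points,
#'   region, defined) and `summary` (per-region mean/SD).
#' @export
spiral_profile <- function(mask, frame, step_deg = 45, regions = NULL,
                           delta_deg = 2, min_radius_um = NULL,
                           bridge_gap_um = NULL) {
  stopifnot(step_deg > 0)
  coords <- spiral_coords(mask, frame)
  tmax <- max(coords$theta)
  n_end <- floor((tmax + delta_deg / 2) / step_deg)
  grid <- (0:n_end) * step_deg
  fr <- list(lateral = 0.9, middle = 0.5, medial = 0.1)
  rows <- lapply(grid, function(th)
    width_thickness_at(mask, coords, th, delta_deg, min_radius_um, fr,
                       bridge_gap_um))
  samples <- data.frame(
    theta_deg = grid,
    width_um = vapply(rows, function(r) r$width, numeric(1)),
    thickness_lateral_um = vapply(rows, function(r)
      r$thickness[["lateral"]], numeric(1)),
    thickness_middle_um = vapply(rows, function(r)
      r$thickness[["middle"]], numeric(1)),
    thickness_medial_um = vapply(rows, function(r)
      r$thickness[["medial"]], numeric(1)),
    defined = vapply(rows, function(r) r$defined, logical(1)))
  samples$region <- if (is.null(regions)) "all" else
    region_of_angle(grid, regions$angle_bounds_deg)
  meas <- c("width_um", "thickness_lateral_um", "thickness_middle_um",
            "thickness_medial_um")
  sm <- do.call(rbind, lapply(split(samples, samples$region), function(d) {
    row <- data.frame(region = d$region[1],
                      n_samples = nrow(d),
                      n_defined = sum(d$defined),
                      n_undefined = sum(!d$defined))
    for (m in meas) {
      v <- d[[m]][d$defined & !is.na(d[[m]])]
      row[[paste0(m, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(m, "_sd")]] <- if (length(v) > 1) sd(v) else NA_real_
    }
    row
  }))
  rownames(sm) <- NULL
  structure(list(samples = samples, summary = sm, step_deg = step_deg,
                 delta_deg = delta_deg),
            class = "osl_profile")
}

region_of_angle <- function(theta, bounds) {
  c("basal", "middle", "apex")[1 + (theta >= bounds[1]) + (theta >= bounds[2])]
}

#' @export
print.osl_profile <- function(x, ...) {
  cat(sprintf("<osl_profile> %d samples every %g deg (%d undefined)\n",
              nrow(x$samples), x$step_deg, sum(!x$samples$defined)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Plot a width/thickness profile
#'
#' Two stacked panels: radial width vs spiral angle, and the three
#' thickness traces vs spiral angle.
#'
#' @param x An `osl_profile`.
#' @param ... Unused.
#' @export
plot.osl_profile <- function(x, ...) {
  d <- x$samples[x$samples$defined, ]
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(par(op))
  plot(d$theta_deg, d$width_um, type = "b", pch = 16,
       xlab = "spiral angle (deg)", ylab = "width (um)",
       main = "OSL radial width")
  cols <- c(thickness_lateral_um = "firebrick",
            thickness_middle_um = "darkblue",
            thickness_medial_um = "darkgreen")
  yl <- range(unlist(d[names(cols)]), na.rm = TRUE)
  plot(d$theta_deg, d$thickness_middle_um, type = "n", ylim = yl,
       xlab = "spiral angle (deg)", ylab = "thickness (um)",
       main = "OSL thickness (assembly height)")
  for (nm in names(cols)) {
    ok <- !is.na(d[[nm]])
    lines(d$theta_deg[ok], d[[nm]][ok], col = cols[[nm]], type = "b",
          pch = 16, cex = 0.6)
  }
  legend("topright", legend = sub("thickness_(\\w+)_um", "\\1", names(cols)),
         col = cols, lty = 1, pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}
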