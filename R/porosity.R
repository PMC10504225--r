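# The filled-envelope porosity statistic: mesh the porous plate
# (original volume V_o), construct its pore-free envelope by
# morphological closing (filled volume V_f), and evaluate
# p = (V_f - V_o) / V_f * 100%.

#' Fill the pore-free envelope of a plate mask
#'
#' Morphological closing (dilation then erosion) with a Euclidean ball
#' of the given radius, computed exactly via the squared distance
#' transform. Pores of diameter smaller than twice the radius are
#' filled while the global plate shape is followed. The output always
#' contains the input (closing is extensive), is idempotent at fixed
#' radius, and grows with the radius.
#'
#' For thin plate-like structures a spherical ball dips into each pore
#' mouth (leaving a shallow unfilled meniscus of depth
#' `r - sqrt(r^2 - a^2)` for a pore of radius `a`); supplying
#' `axial_radius_um` flattens the structuring element into an oblate
#' ellipsoid (in-plane radius `closing_radius_um`, axial semi-axis
#' `axial_radius_um`, axial = the z lattice direction) that fills pore
#' mouths nearly flush while still following the plate shape.
#'
#' @param mask A `binary_mask`.
#' @param closing_radius_um In-plane structuring-element radius in µm
#'   (at least one voxel).
#' @param axial_radius_um Optional axial semi-axis in µm (default: the
#'   spherical ball, i.e. equal to `closing_radius_um`). Values below
#'   the voxel size flatten the element to a disc, i.e. per-slice
#'   in-plane closing, which fills pores in plate-like structures flush
#'   with the plate faces.
#' @param exclusion_mask Optional `binary_mask` of the other plate: if
#'   the filled envelope would intersect it the closing has bridged the
#'   inter-plate gap and an error advising a smaller radius is raised.
#' @param method `"ball"` (default): voxel-space morphological closing
#'   as described above. `"plate"`: a height-field shrink-wrap for
#'   plate-like sheets - the top and bottom surface height maps of the
#'   (single) sheet are closed in-plane with a flat disc of radius
#'   `closing_radius_um` and the envelope is everything between them.
#'   This follows a tilted, tapering plate exactly and fills
#'   through-plate pores flush with the faces; it requires each (x,y)
#'   column to cross the sheet at most once (true for any sub-turn
#'   angular piece of the lamina).
#' @return A `binary_mask` (the filled envelope).
#' @export
fill_envelope <- function(mask, closing_radius_um, axial_radius_um = NULL,
                          exclusion_mask = NULL,
                          method = c("ball", "plate")) {
  stopifnot(inherits(mask, "binary_mask"))
  method <- match.arg(method)
  vox <- mask$voxel_size_um
  if (closing_radius_um < vox)
    stop("closing_radius_um must be at least one voxel")
  if (is.null(axial_radius_um)) axial_radius_um <- closing_radius_um
  if (axial_radius_um <= 0)
    stop("axial_radius_um must be positive")
  v <- mask$values
  if (!any(v)) return(mask)
  if (method == "plate") {
    out <- plate_wrap(v, closing_radius_um / vox)
    if (!is.null(exclusion_mask) && any(out & exclusion_mask$values))
      stop(sprintf(
        "closing radius %g um merges the plate with the excluded structure; use a smaller radius",
        closing_radius_um))
    return(binary_mask(out, vox, mask$origin,
                       provenance = c(mask$provenance,
                                      list(closing_radius_um =
                                             closing_radius_um,
                                           envelope_method = "plate"))))
  }
  r <- closing_radius_um / vox
  cz <- axial_radius_um / vox
  w <- c(1, 1, (r / cz)^2)
  pw <- as.integer(ceiling(r)) + 1L
  d <- dim(v)
  # operate on the padded bounding box only
  rng <- lapply(1:3, function(a) {
    pres <- apply(v, a, any)
    c(max(1L, min(which(pres)) - pw), min(d[a], max(which(pres)) + pw))
  })
  sub <- v[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
           rng[[3]][1]:rng[[3]][2], drop = FALSE]
  ds <- dim(sub)
  dp <- ds + 2L * pw
  pad <- array(FALSE, dp)
  pad[pw + seq_len(ds[1]), pw + seq_len(ds[2]), pw + seq_len(ds[3])] <- sub
  r2 <- r * r + 1e-9
  dil <- cpp_sqedt(as.logical(pad), as.integer(dp), w) <= r2
  closed <- cpp_sqedt(!dil, as.integer(dp), w) > r2
  dim(closed) <- dp
  out <- array(FALSE, d)
  out[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
      rng[[3]][1]:rng[[3]][2]] <-
    closed[pw + seq_len(ds[1]), pw + seq_len(ds[2]), pw + seq_len(ds[3])]
  if (!is.null(exclusion_mask) && any(out & exclusion_mask$values))
    stop(sprintf(
      "closing radius %g um merges the plate with the excluded structure; use a smaller radius",
      closing_radius_um))
  binary_mask(out, vox, mask$origin,
              provenance = c(mask$provenance,
                             list(closing_radius_um = closing_radius_um,
                                  axial_radius_um = axial_radius_um,
                                  envelope_method = "ball")))
}

# Height-field envelope of an angular piece of the lamina. Pieces
# sweeping 180 degrees or more are split into angular sub-sectors
# first: a piece spanning a full turn has (x,y) columns that cross the
# sheet twice (once per turn), which would make the column height span
# both turns and flood the inter-turn space. Requires a frame with a
# pitch for the split; sub-turn pieces work without one.
sector_envelope <- function(mask, closing_radius_um, frame = NULL) {
  if (is.null(frame))
    return(fill_envelope(mask, closing_radius_um, method = "plate"))
  co <- spiral_coords(mask, frame)
  if (!length(co$theta))
    return(fill_envelope(mask, closing_radius_um, method = "plate"))
  span <- max(co$theta) - min(co$theta)
  nb <- max(1L, ceiling((span + 1e-6) / 180))
  if (nb == 1L)
    return(fill_envelope(mask, closing_radius_um, method = "plate"))
  bin <- pmin(nb, floor((co$theta - min(co$theta)) / (span / nb)) + 1L)
  acc <- array(FALSE, dim(mask$values))
  for (b in seq_len(nb)) {
    idx <- co$idx[bin == b, , drop = FALSE]
    if (!nrow(idx)) next
    sub <- array(FALSE, dim(mask$values))
    sub[idx] <- TRUE
    acc <- acc | fill_envelope(
      binary_mask(sub, mask$voxel_size_um, mask$origin),
      closing_radius_um, method = "plate")$values
  }
  binary_mask(acc, mask$voxel_size_um, mask$origin,
              provenance = c(mask$provenance,
                             list(closing_radius_um = closing_radius_um,
                                  envelope_method = "plate",
                                  angular_sectors = nb)))
}

# height-field shrink-wrap of a single sheet: the in-plane support is
# closed with a flat disc of radius r_vox (fills pore columns while
# following the plate outline), and the top/bottom surface height maps
# are reconstructed over the filled columns by neighbour-mean infill -
# an unbiased local interpolation that follows a tilted, tapering,
# stair-quantized surface where a grayscale closing would bias the
# reconstruction near curvature.
plate_wrap <- function(v, r_vox) {
  d <- dim(v)
  ex <- cpp_column_extents(as.logical(v), as.integer(d))
  pw <- as.integer(ceiling(r_vox)) + 1L
  dp <- d[1:2] + 2L * pw
  sup <- matrix(0, dp[1], dp[2])
  inside <- cbind(rep(pw + seq_len(d[1]), d[2]),
                  rep(pw + seq_len(d[2]), each = d[1]))
  top <- matrix(as.numeric(ex$top), d[1], d[2])
  bot <- matrix(as.numeric(ex$bottom), d[1], d[2])
  known0 <- top > 0
  sup[inside] <- as.numeric(known0)
  # binary closing of the support map with a disc
  sup_cl <- -cpp_disc_max(-cpp_disc_max(sup, r_vox), r_vox) > 0.5
  sup_cl <- matrix(sup_cl, dp[1], dp[2])[pw + seq_len(d[1]),
                                         pw + seq_len(d[2])]
  domain <- sup_cl | known0
  top[!known0] <- NA_real_
  bot[!known0] <- NA_real_
  top_f <- cpp_fill_heights(top, known0, domain)
  bot_f <- cpp_fill_heights(bot, known0, domain)
  top_i <- floor(top_f + 0.5)
  bot_i <- floor(bot_f + 0.5)
  filled <- domain & !is.na(top_i)
  out <- array(FALSE, d)
  for (k in seq_len(d[3]))
    out[, , k] <- filled & bot_i <= k & k <= top_i
  out | v
}

#' Porosity from original and filled volumes
#'
#' Evaluates `p = (V_f - V_o) / V_f * 100`. Small violations of
#' `V_o <= V_f` (up to 0.5%, mesh noise) are clamped to 0 with a
#' warning; larger violations indicate a pipeline fault and error.
#'
#' @param V_o Original (porous) volume.
#' @param V_f Filled (pore-free) volume; must be positive.
#' @return Porosity in percent, in \[0, 100\].
#' @export
porosity <- function(V_o, V_f) {
  if (!is.numeric(V_o) || !is.numeric(V_f)) stop("volumes must be numeric")
  if (V_f <= 0) stop("filled volume V_f must be positive")
  if (V_o < 0) stop("original volume V_o must be non-negative")
  if (V_o > V_f) {
    if (V_o <= 1.005 * V_f) {
      warning("V_o slightly exceeds V_f (mesh noise); porosity clamped to 0")
      return(0)
    }
    stop("V_o exceeds V_f by more than 0.5%: the envelope is smaller than the material (pipeline fault)")
  }
  (V_f - V_o) / V_f * 100
}

#' Per-region filled-envelope porosity of a plate
#'
#' For each region: restrict the plate mask, extract its watertight
#' surface, (optionally) decimate, and take the divergence-theorem
#' volume as V_o; fill the envelope by morphological closing, mesh it
#' the same way for V_f; evaluate the porosity. The voxel-count
#' porosity is carried alongside as a cross-check and a discrepancy
#' beyond 3% between mesh and voxel volumes is flagged.
#'
#' @param plate_mask A `binary_mask` of one plate.
#' @param regions A `region_partition` on the same lattice, or `NULL`
#'   to measure the whole plate as one region `"all"`.
#' @param closing_radius_um In-plane structuring-element radius for
#'   [fill_envelope()]; choose it from the observed pore sizes (several
#'   times the largest pore radius, but smaller than the modiolar
#'   radius).
#' @param axial_radius_um Optional axial semi-axis (see
#'   [fill_envelope()]); for thin plates about half the plate thickness
#'   avoids the pore-mouth meniscus bias of a spherical ball.
#' @param simplify_fraction Optional triangle fraction for
#'   [simplify_mesh()] (`NULL` = no decimation).
#' @param exclusion_mask Optional other-plate mask forwarded to
#'   [fill_envelope()].
#' @param plate Label recorded in the result rows.
#' @param envelope_method Envelope construction, `"ball"` or `"plate"`
#'   (see [fill_envelope()]); the height-field `"plate"` wrap is the
#'   right choice for per-region lamina pieces.
#' @param frame Optional `spiral_frame`; with the `"plate"` method,
#'   pieces sweeping 180° or more are split into angular sub-sectors
#'   about this frame before wrapping (required for full-turn pieces).
#' @return A data frame of class `porosity_result`: one row per
#'   non-empty region with V_o, V_f, porosity, voxel counts, and the
#'   parameters used.
#' @export
plate_porosity <- function(plate_mask, regions = NULL, closing_radius_um,
                           axial_radius_um = NULL,
                           simplify_fraction = NULL, exclusion_mask = NULL,
                           plate = "plate",
                           envelope_method = c("ball", "plate"),
                           frame = NULL) {
  envelope_method <- match.arg(envelope_method)
  stopifnot(inherits(plate_mask, "binary_mask"))
  vox <- plate_mask$voxel_size_um
  region_sets <- if (is.null(regions)) {
    list(all = plate_mask$values)
  } else {
    stopifnot(inherits(regions, "region_partition"))
    rn <- regions$region_names
    setNames(lapply(seq_along(rn), function(i)
      plate_mask$values & regions$labels == i), rn)
  }
  out <- list()
  for (rn in names(region_sets)) {
    sel <- region_sets[[rn]]
    n_mat <- sum(sel)
    if (n_mat == 0) {
      message(sprintf("region %s of plate %s is empty; skipped", rn, plate))
      next
    }
    # crop to the region bounding box (with margin) for speed
    d <- dim(sel)
    rng <- lapply(1:3, function(a) {
      pres <- apply(sel, a, any)
      c(max(1L, min(which(pres)) - 2L), min(d[a], max(which(pres)) + 2L))
    })
    sub <- sel[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
               rng[[3]][1]:rng[[3]][2], drop = FALSE]
    orig <- plate_mask$origin + (vapply(rng, `[`, numeric(1), 1) - 1) * vox
    m <- binary_mask(sub, vox, orig)
    excl <- if (is.null(exclusion_mask)) NULL else
      binary_mask(exclusion_mask$values[
        rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
        rng[[3]][1]:rng[[3]][2], drop = FALSE], vox, orig)
    mesh_o <- extract_surface(m)
    env <- if (envelope_method == "plate")
      sector_envelope(m, closing_radius_um, frame)
    else fill_envelope(m, closing_radius_um, axial_radius_um,
                       exclusion_mask = excl)
    if (!is.null(excl) && any(env$values & excl$values))
      stop(sprintf(
        "closing radius %g um merges the plate with the excluded structure; use a smaller radius",
        closing_radius_um))
    mesh_f <- extract_surface(env)
    if (!is.null(simplify_fraction)) {
      mesh_o <- simplify_mesh(mesh_o, simplify_fraction)
      mesh_f <- simplify_mesh(mesh_f, simplify_fraction)
    }
    V_o <- mesh_volume(mesh_o)
    V_f <- mesh_volume(mesh_f)
    n_env <- sum(env$values)
    p <- porosity(V_o, V_f)
    p_vox <- 100 * (n_env - n_mat) / n_env
    vox3 <- vox^3
    if (abs(V_o - n_mat * vox3) / (n_mat * vox3) > 0.03 ||
        abs(V_f - n_env * vox3) / (n_env * vox3) > 0.03)
      warning(sprintf(
        "mesh and voxel-count volumes differ by more than 3%% for plate %s region %s",
        plate, rn))
    out[[length(out) + 1L]] <- data.frame(
      plate = plate, region = rn, V_o_um3 = V_o, V_f_um3 = V_f,
      p_percent = p, n_material_voxels = n_mat, n_envelope_voxels = n_env,
      p_voxel_percent = p_vox, closing_radius_um = closing_radius_um,
      axial_radius_um = if (is.null(axial_radius_um)) closing_radius_um
        else axial_radius_um,
      simplify_fraction = if (is.null(simplify_fraction)) NA_real_
        else simplify_fraction)
  }
  res <- do.call(rbind, out)
  class(res) <- c("porosity_result", class(res))
  res
}

#' @export
print.porosity_result <- function(x, ...) {
  cat("<porosity_result>\n")
  print(as.data.frame(x)[, c("plate", "region", "V_o_um3", "V_f_um3",
                             "p_percent", "p_voxel_percent")],
        digits = 4, row.names = FALSE)
  invisible(x)
}
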