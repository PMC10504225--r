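# Spatial distribution of pores: pore space as the envelope-minus-
# material set, and pore fraction per radial band and angular sector.

#' Pore space of a plate
#'
#' The set difference envelope AND NOT material, with 26-connected
#' components labelled as individual pores.
#'
#' @param plate_mask A `binary_mask` of the (porous) plate.
#' @param envelope A `binary_mask` of the filled envelope; must contain
#'   the plate mask.
#' @return List of class `pore_space`: `mask` (a `binary_mask` of the
#'   pore voxels), `labels` (integer component array), `n_pores`.
#' @export
pore_space <- function(plate_mask, envelope) {
  stopifnot(inherits(plate_mask, "binary_mask"),
            inherits(envelope, "binary_mask"))
  if (!same_lattice(plate_mask, envelope))
    stop("plate mask and envelope are not on the same lattice")
  if (any(plate_mask$values & !envelope$values))
    stop("envelope does not contain the plate mask")
  pores <- envelope$values & !plate_mask$values
  lab <- cpp_label_components(as.logical(pores), as.integer(dim(pores)), 26L)
  structure(list(
    mask = binary_mask(pores, plate_mask$voxel_size_um, plate_mask$origin,
                       provenance = list(source = "pore_space")),
    labels = array(lab, dim(pores)),
    n_pores = attr(lab, "n")), class = "pore_space")
}

#' @export
print.pore_space <- function(x, ...) {
  cat(sprintf("<pore_space> %d pore voxels in %d pores\n",
              sum(x$mask$values), x$n_pores))
  invisible(x)
}

#' Pore fraction per radial band and angular sector
#'
#' Within each angular sector (by default the basal/middle/apex
#' regions) the local radial span of the envelope is estimated per
#' fine angular bin, every voxel is assigned its local radial fraction
#' in \[0, 1\], and the span is split into `n_bands` equal bands
#' (named medial/middle/lateral for the default three). The pore
#' fraction of a band is pore voxels / envelope voxels in that band.
#'
#' @param pores A `pore_space` (or a `binary_mask` of pore voxels).
#' @param envelope A `binary_mask` of the filled envelope.
#' @param frame A `spiral_frame`.
#' @param n_bands Number of radial bands (>= 2).
#' @param regions Optional `region_partition` supplying the angular
#'   sectors; `NULL` uses a single sector `"all"`.
#' @param theta_bin_deg Fine angular bin for the local radial span.
#' @return A data frame of class `pore_map`: sector, band,
#'   envelope_voxels, pore_voxels, pore_fraction, n_pores.
#' @export
radial_pore_fraction <- function(pores, envelope, frame, n_bands = 3,
                                 regions = NULL, theta_bin_deg = 5) {
  if (inherits(pores, "pore_space")) {
    pore_labels <- pores$labels
    pores <- pores$mask
  } else pore_labels <- NULL
  stopifnot(inherits(pores, "binary_mask"),
            inherits(envelope, "binary_mask"), n_bands >= 2)
  if (any(pores$values & !envelope$values))
    stop("pore voxels outside the envelope")
  co <- spiral_coords(envelope, frame)
  is_pore <- pores$values[co$idx]
  bin <- floor(co$theta / theta_bin_deg)
  inner <- tapply(co$rho, bin, min)
  outer <- tapply(co$rho, bin, max)
  key <- match(as.character(bin), names(inner))
  span <- pmax(outer[key] - inner[key], pores$voxel_size_um)
  u <- pmin(pmax((co$rho - inner[key]) / span, 0), 1)
  band <- pmin(n_bands, floor(u * n_bands) + 1L)
  band_names <- if (n_bands == 3) c("medial", "middle", "lateral")
    else paste0("band_", seq_len(n_bands))
  sector <- if (is.null(regions)) rep("all", length(u)) else {
    rl <- regions$labels[co$idx]
    # envelope voxels outside the material partition inherit the
    # nearest angular sector from the bounds
    miss <- rl == 0L
    if (any(miss))
      rl[miss] <- match(region_of_angle(co$theta[miss],
                                        regions$angle_bounds_deg),
                        regions$region_names)
    regions$region_names[rl]
  }
  df <- expand.grid(sector = unique(sector), band = band_names,
                    stringsAsFactors = FALSE)
  df$envelope_voxels <- mapply(function(s, bn)
    sum(sector == s & band == match(bn, band_names)), df$sector, df$band)
  df$pore_voxels <- mapply(function(s, bn)
    sum(is_pore & sector == s & band == match(bn, band_names)),
    df$sector, df$band)
  df$pore_fraction <- ifelse(df$envelope_voxels > 0,
                             df$pore_voxels / df$envelope_voxels, NA_real_)
  if (any(df$envelope_voxels == 0))
    df$pore_fraction[df$envelope_voxels == 0] <- NA_real_
  # count pores by component centroid
  if (!is.null(pore_labels)) {
    pl <- pore_labels[co$idx]
    pc <- pl[is_pore & pl > 0L]
    if (length(pc)) {
      cu <- tapply(u[is_pore & pl > 0L], pc, mean)
      cth <- tapply(co$theta[is_pore & pl > 0L], pc, mean)
      cband <- band_names[pmin(n_bands, floor(cu * n_bands) + 1L)]
      csector <- if (is.null(regions)) rep("all", length(cu)) else
        region_of_angle(cth, regions$angle_bounds_deg)
      df$n_pores <- mapply(function(s, bn)
        sum(csector == s & cband == bn), df$sector, df$band)
    } else df$n_pores <- 0L
  } else df$n_pores <- NA_integer_
  class(df) <- c("pore_map", class(df))
  df
}

#' @export
print.pore_map <- function(x, ...) {
  cat("<pore_map>\n")
  print(as.data.frame(x), digits = 3, row.names = FALSE)
  invisible(x)
}
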