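# Segmentation: global thresholding of the bone/soft-tissue contrast,
# small-component artifact removal, geometric separation of the
# vestibular (VP) and tympanic (TP) plates about the gap mid-surface,
# and angle-based basal/middle/apex partitioning.

#' Otsu threshold of a numeric sample
#'
#' Two-class histogram threshold maximising the between-class variance
#' over 256 bins.
#'
#' @param values Numeric vector (or array) of gray values.
#' @param n_bins Number of histogram bins.
#' @return Threshold on the value scale.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (diff(rng) == 0)
    stop("constant-valued input: no separable classes for an automatic threshold")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(pmin(pmax(findInterval(values, br,
                                                  all.inside = TRUE), 1L),
                                n_bins), nbins = n_bins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[n_bins]
  mt <- m[n_bins]
  w1 <- w[-n_bins]
  m1 <- m[-n_bins]
  valid <- w1 > 0 & w1 < n
  bc <- rep(-Inf, n_bins - 1L)
  bc[valid] <- (mt * w1[valid] - n * m1[valid])^2 /
    (w1[valid] * (n - w1[valid]))
  br[which.max(bc) + 1L]
}

#' Binarize a grayscale volume
#'
#' Material is where the gray value is at least the threshold. With
#' `threshold = "auto"` a two-class (Otsu) histogram threshold is
#' selected. Re-binarizing the 0/1 cast of the result at 0.5 returns
#' the same mask.
#'
#' @param vol A `gray_volume`.
#' @param threshold Numeric threshold, or `"auto"`.
#' @return A `binary_mask` with the threshold recorded in its
#'   provenance.
#' @export
binarize <- function(vol, threshold = "auto") {
  stopifnot(inherits(vol, "gray_volume"))
  if (identical(threshold, "auto")) {
    thr <- otsu_threshold(vol$values)
    method <- "otsu"
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    thr <- threshold
    method <- "manual"
  }
  m <- vol$values >= thr
  if (!any(m))
    warning(sprintf("threshold %g is above the global maximum %g: empty mask",
                    thr, max(vol$values)))
  binary_mask(m, vol$voxel_size_um, vol$origin,
              provenance = list(threshold = thr, threshold_method = method))
}

#' Remove small-component artifacts
#'
#' Deletes 26-connected components smaller than `min_component_voxels`;
#' all other voxels are untouched. Never adds voxels and is idempotent.
#'
#' @param mask A `binary_mask`.
#' @param min_component_voxels Minimum surviving component size (>= 1).
#' @return A `binary_mask`.
#' @export
remove_artifacts <- function(mask, min_component_voxels) {
  stopifnot(inherits(mask, "binary_mask"), min_component_voxels >= 1)
  if (!any(mask$values)) return(mask)
  lab <- cpp_label_components(as.logical(mask$values),
                              as.integer(dim(mask$values)), 26L)
  sizes <- attr(lab, "sizes")
  keep <- which(sizes >= min_component_voxels)
  out <- array(lab %in% keep & lab > 0L, dim(mask$values))
  binary_mask(out, mask$voxel_size_um, mask$origin,
              provenance = c(mask$provenance,
                             list(min_component_voxels = min_component_voxels,
                                  components_removed =
                                    length(sizes) - length(keep))))
}

#' Split the lamina into vestibular and tympanic plates
#'
#' Each material voxel is assigned by the sign of its axial coordinate
#' relative to the gap mid-surface of the spiral sweep, estimated per
#' angular bin as the midpoint of the local axial extent. The
#' vestibular plate is the apical (+axis) side. The two outputs
#' partition the input exactly; inter-plate pillar voxels are split at
#' the mid-surface.
#'
#' @param mask A `binary_mask`.
#' @param frame A `spiral_frame` (with pitch for multi-turn masks).
#' @param bin_deg Angular bin width for the mid-surface estimate.
#' @param max_dist_um Optional cutoff: voxels farther than this from
#'   the mid-surface are counted and reported via the
#'   `far_voxel_count` attribute (never silently dropped).
#' @return List with components `vp` and `tp` (both `binary_mask`).
#' @export
split_plates <- function(mask, frame, bin_deg = 1, max_dist_um = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$values)) stop("cannot split an empty mask")
  co <- spiral_coords(mask, frame)
  bin <- floor(co$theta / bin_deg)
  mid_by_bin <- vapply(split(co$ax, bin), function(z)
    (quantile(z, 0.01, names = FALSE) + quantile(z, 0.99, names = FALSE)) / 2,
    numeric(1))
  mid <- mid_by_bin[match(as.character(bin), names(mid_by_bin))]
  up <- co$ax > mid
  d <- dim(mask$values)
  vp <- array(FALSE, d)
  tp <- array(FALSE, d)
  vp[co$idx[up, , drop = FALSE]] <- TRUE
  tp[co$idx[!up, , drop = FALSE]] <- TRUE
  far <- 0L
  if (!is.null(max_dist_um)) {
    far <- sum(abs(co$ax - mid) > max_dist_um)
    if (far > 0)
      message(sprintf(
        "%d voxel(s) lie farther than %g um from the gap mid-surface",
        far, max_dist_um))
  }
  prov <- c(mask$provenance, list(plate_split_bin_deg = bin_deg))
  out <- list(
    vp = binary_mask(vp, mask$voxel_size_um, mask$origin,
                     provenance = c(prov, list(plate = "vp"))),
    tp = binary_mask(tp, mask$voxel_size_um, mask$origin,
                     provenance = c(prov, list(plate = "tp"))))
  attr(out, "far_voxel_count") <- far
  out
}

#' Partition a mask into basal/middle/apex regions by spiral angle
#'
#' Voxels below the first bound are basal, between the bounds middle,
#' at or above the second bound apex. The three labels partition the
#' mask exactly.
#'
#' @param mask A `binary_mask`.
#' @param frame A `spiral_frame`.
#' @param angle_bounds_deg Two increasing cut angles in degrees
#'   (default 360 and 630).
#' @return An object of class `region_partition`: integer label array
#'   (0 background, 1 basal, 2 middle, 3 apex), the bounds, and region
#'   names.
#' @export
partition_regions <- function(mask, frame, angle_bounds_deg = c(360, 630)) {
  stopifnot(inherits(mask, "binary_mask"), length(angle_bounds_deg) == 2)
  b <- as.numeric(angle_bounds_deg)
  if (!(b[1] > 0 && b[2] > b[1]))
    stop("angle bounds must satisfy 0 < bound1 < bound2")
  co <- spiral_coords(mask, frame)
  tmax <- max(co$theta)
  if (b[2] >= tmax + 1)
    stop(sprintf(
      "angle bounds (%g, %g) lie outside the observed angular range [%.1f, %.1f]",
      b[1], b[2], min(co$theta), tmax))
  lab <- array(0L, dim(mask$values))
  lab[co$idx] <- 1L + (co$theta >= b[1]) + (co$theta >= b[2])
  structure(list(labels = lab, angle_bounds_deg = b,
                 region_names = c("basal", "middle", "apex"),
                 voxel_size_um = mask$voxel_size_um, origin = mask$origin),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  n <- tabulate(x$labels[x$labels > 0L], 3L)
  cat(sprintf(
    "<region_partition> bounds %g/%g deg: basal %d, middle %d, apex %d voxels\n",
    x$angle_bounds_deg[1], x$angle_bounds_deg[2], n[1], n[2], n[3]))
  invisible(x)
}
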