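# Core volumetric containers: grayscale volumes and binary masks on an
# isotropic voxel lattice. Physical coordinates are in micrometres; the
# `origin` is the physical position of the centre of voxel (1,1,1).

#' Grayscale volume
#'
#' A 3D scalar grid with isotropic voxel size. Values are stored as
#' 16-bit-style digital numbers (0-65535) but any numeric range works.
#'
#' @param values 3D numeric array.
#' @param voxel_size_um Isotropic voxel edge length in micrometres.
#' @param origin Physical coordinate (µm) of the centre of voxel (1,1,1).
#' @return An object of class `gray_volume`.
#' @export
gray_volume <- function(values, voxel_size_um, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1 ||
      voxel_size_um <= 0)
    stop("voxel_size_um must be a single positive number")
  structure(list(values = values, voxel_size_um = voxel_size_um,
                 origin = as.numeric(origin)),
            class = "gray_volume")
}

#' Binary mask
#'
#' A 3D logical grid on the same lattice as its source volume, with the
#' segmentation provenance (threshold, cleanup parameters) attached.
#'
#' @param values 3D logical array (`TRUE` = material).
#' @param voxel_size_um Isotropic voxel edge length in micrometres.
#' @param origin Physical coordinate (µm) of the centre of voxel (1,1,1).
#' @param provenance Named list of parameters that produced the mask.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, voxel_size_um, origin = c(0, 0, 0),
                        provenance = list()) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (!is.logical(values)) {
    values <- array(as.logical(values), dim(values))
  }
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1 ||
      voxel_size_um <= 0)
    stop("voxel_size_um must be a single positive number")
  structure(list(values = values, voxel_size_um = voxel_size_um,
                 origin = as.numeric(origin), provenance = provenance),
            class = "binary_mask")
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<gray_volume> %d x %d x %d voxels @ %g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  cat(sprintf("  value range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask> %d x %d x %d voxels @ %g um, %d material (%.2f%%)\n",
              d[1], d[2], d[3], x$voxel_size_um, sum(x$values),
              100 * mean(x$values)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

# physical coordinates (µm, n x 3) of voxel indices (n x 3, 1-based)
voxel_centers_um <- function(idx, voxel_size_um, origin) {
  sweep((idx - 1) * voxel_size_um, 2, origin, "+")
}

# index coordinates of all TRUE voxels as an n x 3 matrix
mask_indices <- function(mask) {
  which(mask$values, arr.ind = TRUE)
}

same_lattice <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$voxel_size_um, b$voxel_size_um)) &&
    isTRUE(all.equal(a$origin, b$origin))
}
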