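# File formats: multi-page TIFF for volumes and masks (one page per
# z-slice, z ascending), binary STL for meshes, JSON sidecars for
# lattice metadata and provenance. All readers round-trip the package's
# own writers.

sidecar_path <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  else paste0(path, ".json")
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE)
  else NULL
}

#' Write a grayscale volume as a 16-bit multi-page TIFF
#'
#' One page per z-slice, z ascending. Values are clamped to
#' \[0, 65535\] and quantised to 16-bit digital numbers. A JSON sidecar
#' (same name, `.json`) records the voxel size and origin.
#'
#' @param vol A `gray_volume`.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "gray_volume"))
  v <- pmin(pmax(vol$values, 0), 65535)
  pages <- lapply(seq_len(dim(v)[3]), function(k) round(v[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  write_sidecar(path, list(kind = "gray_volume",
                           voxel_size_um = vol$voxel_size_um,
                           origin = vol$origin, dim = dim(v)))
  invisible(path)
}

#' Read a grayscale volume written by [write_volume_tiff()]
#'
#' @param path `.tif` path.
#' @param voxel_size_um Voxel size; taken from the JSON sidecar when
#'   present.
#' @return A `gray_volume` with integer 16-bit digital numbers.
#' @export
read_volume_tiff <- function(path, voxel_size_um = NULL) {
  meta <- read_sidecar(path)
  if (is.null(voxel_size_um)) {
    if (is.null(meta)) stop("no sidecar found; supply voxel_size_um")
    voxel_size_um <- meta$voxel_size_um
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- round(pages[[k]] * 65535)
  origin <- if (!is.null(meta)) meta$origin else c(0, 0, 0)
  gray_volume(arr, voxel_size_um, origin)
}

#' Write a binary mask as an 8-bit multi-page TIFF (0/255)
#'
#' @param mask A `binary_mask`.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  v <- mask$values
  pages <- lapply(seq_len(dim(v)[3]), function(k) (v[, , k]) * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  write_sidecar(path, list(kind = "binary_mask",
                           voxel_size_um = mask$voxel_size_um,
                           origin = mask$origin, dim = dim(v),
                           provenance = mask$provenance))
  invisible(path)
}

#' Read a binary mask written by [write_mask_tiff()]
#'
#' @param path `.tif` path.
#' @param voxel_size_um Voxel size; taken from the JSON sidecar when
#'   present.
#' @return A `binary_mask`.
#' @export
read_mask_tiff <- function(path, voxel_size_um = NULL) {
  meta <- read_sidecar(path)
  if (is.null(voxel_size_um)) {
    if (is.null(meta)) stop("no sidecar found; supply voxel_size_um")
    voxel_size_um <- meta$voxel_size_um
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(FALSE, c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                        length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] > 0.5
  origin <- if (!is.null(meta)) meta$origin else c(0, 0, 0)
  prov <- if (!is.null(meta) && !is.null(meta$provenance))
    as.list(meta$provenance) else list()
  binary_mask(arr, voxel_size_um, origin, provenance = prov)
}

#' Write a mesh as binary STL
#'
#' @param mesh A `surface_mesh`.
#' @param path Output `.stl` path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("oslmorph binary STL", width = 80, flag = "-"))
  writeBin(header[1:80], con)
  nt <- nrow(mesh$triangles)
  writeBin(as.integer(nt), con, size = 4, endian = "little")
  V <- mesh$vertices
  F <- mesh$triangles
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  # 12 float32 per facet (normal, v1, v2, v3) then a uint16 attribute;
  # assembled as raw and written in one call
  block <- t(cbind(n, a, b, c_))  # 12 x nt
  fl <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
  rec <- matrix(as.raw(0), 50, nt)
  rec[1:48, ] <- matrix(fl, 48, nt)
  writeBin(as.vector(rec), con)
  invisible(path)
}

#' Read a binary STL file
#'
#' Vertices repeated across facets are merged by exact coordinate
#' match, so meshes written by [write_stl()] round-trip with their
#' connectivity restored.
#'
#' @param path `.stl` path.
#' @return A `surface_mesh`.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  rec <- matrix(readBin(con, "raw", n = 50 * nt), 50, nt)
  fl <- matrix(readBin(as.vector(rec[1:48, , drop = FALSE]), "numeric",
                       n = 12 * nt, size = 4, endian = "little"), 12, nt)
  # rows 4:12 are the three vertices of each facet
  verts <- matrix(0, nt * 3, 3)
  verts[seq(1, 3 * nt, by = 3), ] <- t(fl[4:6, , drop = FALSE])
  verts[seq(2, 3 * nt, by = 3), ] <- t(fl[7:9, , drop = FALSE])
  verts[seq(3, 3 * nt, by = 3), ] <- t(fl[10:12, , drop = FALSE])
  key <- paste(verts[, 1], verts[, 2], verts[, 3], sep = "/")
  uid <- !duplicated(key)
  ids <- match(key, key[uid])
  surface_mesh(verts[uid, , drop = FALSE],
               matrix(ids, ncol = 3, byrow = TRUE))
}
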