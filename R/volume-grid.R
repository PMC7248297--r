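#' 3D volume with voxel-to-millimeter affine
#'
#' A `volume_grid` is the carrier for gray-matter images, binary masks and
#' BSR maps: a 3D numeric array plus a 4x4 affine matrix mapping 0-based
#' voxel indices (i, j, k) to RAS+ millimeter coordinates, as in the NIfTI-1
#' standard.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 numeric matrix, invertible, last row (0, 0, 0, 1).
#' @return An object of class `volume_grid` with elements `data` and
#'   `affine`.
#' @export
volume_grid <- function(data, affine) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  affine <- unname(as.matrix(affine))
  if (!identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("`affine` is not invertible", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, affine = affine), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  vs <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  cat(sprintf("<volume_grid> %d x %d x %d voxels, voxel size %s mm\n",
              d[1], d[2], d[3], paste(signif(vs, 4), collapse = " x ")))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' Map voxel indices to millimeter coordinates
#'
#' @param affine 4x4 affine matrix (voxel index to mm), or a `volume_grid`.
#' @param ijk integer matrix (n x 3) of 1-based voxel indices, or a length-3
#'   vector. Indices are converted to the 0-based convention of the affine.
#' @return n x 3 matrix of (x, y, z) millimeter coordinates.
#' @export
voxel_to_mm <- function(affine, ijk) {
  if (inherits(affine, "volume_grid")) affine <- affine$affine
  ijk <- rbind(ijk)
  stopifnot(ncol(ijk) == 3L)
  h <- cbind(ijk - 1, 1) %*% t(affine)   # 0-based homogeneous coords
  unname(h[, 1:3, drop = FALSE])
}

#' Millimeter coordinates of every voxel in a grid
#'
#' @param vol a `volume_grid`.
#' @return (prod(dim) x 3) matrix of mm coordinates in array (column-major)
#'   order.
#' @keywords internal
grid_mm_coords <- function(vol) {
  d <- dim(vol$data)
  ijk <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  voxel_to_mm(vol$affine, ijk)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file into a [volume_grid()]. Volumes containing
#' non-finite voxels are rejected with the offending voxel indices, as are
#' files whose affine is singular.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param binary if `TRUE`, require the volume to be a 0/1 mask (values are
#'   binarised at != 0 after checking they are already in {0, 1}).
#' @return A `volume_grid`.
#' @export
read_volume <- function(path, binary = FALSE) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), code = NULL, imagedim = NULL)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  bad <- which(!is.finite(arr))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(arr))
    stop(sprintf("volume '%s' contains %d non-finite voxel(s); first at index (%d, %d, %d)",
                 path, length(bad), idx[1], idx[2], idx[3]), call. = FALSE)
  }
  if (binary) {
    if (!all(arr %in% c(0, 1)))
      stop(sprintf("volume '%s' requested as binary mask but contains values outside {0, 1}",
                   path), call. = FALSE)
  }
  volume_grid(arr, unname(as.matrix(aff)))
}

#' Write a NIfTI volume
#'
#' @param vol a `volume_grid`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  img <- RNifti::asNifti(vol$data)
  RNifti::`sform<-`(img, structure(vol$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Check that two grids share shape and affine (tolerance for float round-trip).
same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) && max(abs(a$affine - b$affine)) < tol
}
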