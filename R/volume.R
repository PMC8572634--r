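#' 3D image volume with voxel spacing
#'
#' A minimal container for a 3D scalar image: a numeric array plus the voxel
#' spacing (mm) and the world coordinate of voxel `[1, 1, 1]`'s centre.
#' Intensities are on the Hounsfield-unit (HU) scale before windowing. Axis
#' order is (x, y, z) with axial slices along z; voxel indices are 1-based in
#' R, and voxel centre `i` sits at `origin + (i - 1) * spacing` in world mm.
#'
#' @param data numeric 3D array.
#' @param spacing_mm positive numeric of length 3 (or 1, recycled), mm.
#' @param origin_mm numeric of length 3, world position of the first voxel
#'   centre in mm.
#' @return An object of class `cow_volume` with fields `data`, `spacing_mm`,
#'   `origin_mm`.
#' @examples
#' v <- volume(array(0, c(8, 8, 4)), spacing_mm = 1)
#' dim(v)
#' @export
volume <- function(data, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive finite values")
  if (any(!is.finite(data))) stop("volume data must be finite")
  structure(
    list(data = data, spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm)),
    class = "cow_volume"
  )
}

#' @export
dim.cow_volume <- function(x) dim(x$data)

#' @export
print.cow_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cow_volume> %d x %d x %d, spacing %.3g x %.3g x %.3g mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2],
              x$spacing_mm[3], min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "cow_volume")

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes are on different grids (shape mismatch)")
  if (max(abs(a$spacing_mm - b$spacing_mm)) > 1e-6)
    stop("volumes are on different grids (spacing mismatch)")
  invisible(TRUE)
}

#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' carry the voxel spacing through the NIfTI header (`pixdim`).
#'
#' @param path file path, conventionally `.nii` or `.nii.gz`.
#' @return `read_volume()` returns a [volume()]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  volume(array(as.numeric(img), dim = dim(img)), spacing_mm = sp[1:3])
}

#' @param v a [volume()].
#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume(v))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
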