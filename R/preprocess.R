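#' Resample a volume to isotropic spacing
#'
#' CTA studies are acquired anisotropically; the segmentation pipeline first
#' resamples every volume (and its mask) to a common isotropic grid,
#' by default 0.5 mm in x, y and z. Intensities are interpolated
#' trilinearly; binary masks use nearest-neighbour so labels stay binary.
#' The output grid keeps the input origin and has shape
#' `round(shape * spacing / target)`.
#'
#' @param v a [volume()].
#' @param target_spacing target isotropic spacing in mm (default 0.5).
#' @param method `"linear"` (intensities) or `"nearest"` (masks/labels).
#' @return A [volume()] at `(t, t, t)` mm spacing.
#' @export
resample_isotropic <- function(v, target_spacing = 0.5, method = c("linear", "nearest")) {
  stopifnot(is_volume(v))
  method <- match.arg(method)
  if (!is.numeric(target_spacing) || target_spacing <= 0)
    stop("`target_spacing` must be > 0")
  d <- dim(v$data)
  if (any(d < 2L)) stop("degenerate (zero-extent) axis")
  newdim <- pmax(2L, as.integer(round(d * v$spacing_mm / target_spacing)))
  out <- resample3d_cpp(as.numeric(v$data), d, v$spacing_mm, v$origin_mm,
                        newdim, rep(target_spacing, 3), v$origin_mm,
                        method == "nearest")
  volume(array(out, newdim), rep(target_spacing, 3), v$origin_mm)
}

#' Window CTA intensities to \[0, 1\]
#'
#' Clamps intensities to the `[lo, hi]` HU window (default 0-2000, removing
#' the influence of air/background below 0 and dense bone streaks above
#' 2000) and rescales linearly to \[0, 1\]. Clamping keeps the voxel grid
#' intact, which the reconstruction task requires. The map is idempotent on
#' its output scale: re-windowing an already-windowed volume with the unit
#' window `(lo = 0, hi = 1)` is the identity. Apply exactly once to HU data.
#'
#' @param v a [volume()] in HU.
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @return A [volume()] with values in \[0, 1\].
#' @export
window_intensity <- function(v, lo = 0, hi = 2000) {
  stopifnot(is_volume(v))
  if (!(lo < hi)) stop("`lo` must be < `hi`")
  x <- pmin(pmax(v$data, lo), hi)
  volume((x - lo) / (hi - lo), v$spacing_mm, v$origin_mm)
}

# centre-crop or zero-pad a 2D matrix to side x side
crop_or_pad <- function(m, side, pad_value = 0) {
  d <- dim(m)
  out <- matrix(pad_value, side, side)
  src <- list(); dst <- list()
  for (a in 1:2) {
    if (d[a] >= side) {
      off <- (d[a] - side) %/% 2
      src[[a]] <- seq.int(off + 1L, off + side)
      dst[[a]] <- seq_len(side)
    } else {
      off <- (side - d[a]) %/% 2
      src[[a]] <- seq_len(d[a])
      dst[[a]] <- seq.int(off + 1L, off + d[a])
    }
  }
  out[dst[[1]], dst[[2]]] <- m[src[[1]], src[[2]]]
  out
}

#' Extract axial training patches from a volume/mask pair
#'
#' One patch per axial (z) slice, centre-cropped or zero-padded to
#' `side x side` pixels (zero is the post-windowing background value).
#' Optionally drops slices whose mask is empty.
#'
#' @param v intensity [volume()] (windowed to \[0, 1\]).
#' @param m mask [volume()] on the same grid.
#' @param side patch side length in pixels (default 288).
#' @param drop_empty drop slices with an empty mask (default `FALSE`).
#' @param volume_id identifier recorded in the provenance table.
#' @return An object of class `cow_patchset`: `patches` and `masks`
#'   (parallel lists of `side x side` matrices) and `provenance`
#'   (data.frame with `volume_id`, `slice`).
#' @export
extract_patches <- function(v, m, side = 288L, drop_empty = FALSE,
                            volume_id = "volume") {
  stopifnot(is_volume(v), is_volume(m))
  stopifnot_same_grid(v, m)
  nz <- dim(v$data)[3]
  keep <- seq_len(nz)
  if (drop_empty)
    keep <- keep[vapply(keep, function(k) sum(m$data[, , k]) > 0, logical(1))]
  patches <- lapply(keep, function(k) crop_or_pad(v$data[, , k], side))
  masks <- lapply(keep, function(k) crop_or_pad(m$data[, , k], side))
  structure(
    list(patches = patches, masks = masks,
         provenance = data.frame(volume_id = volume_id, slice = keep),
         side = as.integer(side)),
    class = "cow_patchset"
  )
}

#' @export
print.cow_patchset <- function(x, ...) {
  cat(sprintf("<cow_patchset> %d patches of %dx%d from %d volume(s)\n",
              length(x$patches), x$side, x$side,
              length(unique(x$provenance$volume_id))))
  invisible(x)
}

# concatenate patch sets
c_patchsets <- function(sets) {
  structure(
    list(patches = do.call(c, lapply(sets, `[[`, "patches")),
         masks = do.call(c, lapply(sets, `[[`, "masks")),
         provenance = do.call(rbind, lapply(sets, `[[`, "provenance")),
         side = sets[[1]]$side),
    class = "cow_patchset"
  )
}

# the 8-element dihedral group on matrices: k quarter-turns + optional flip
apply_dihedral <- function(m, k, flip) {
  rot90 <- function(x) t(x[nrow(x):1, , drop = FALSE])
  for (i in seq_len(k %% 4)) m <- rot90(m)
  if (flip) m <- m[nrow(m):1, , drop = FALSE]
  m
}

#' Jointly augment a patch/mask pair by rotation and flipping
#'
#' Applies the same randomly drawn rigid transform — a multiple of 90
#' degrees plus an optional flip (the 8-element dihedral group, so binary
#' masks incur no interpolation) — to both the intensity patch and its mask.
#'
#' @param patch,mask aligned 2D matrices.
#' @param seed integer seed; the transform is deterministic given it.
#' @return `list(patch=, mask=, k=, flip=)`.
#' @export
augment <- function(patch, mask, seed) {
  stopifnot(identical(dim(patch), dim(mask)))
  tr <- with_seed(seed, list(k = sample(0:3, 1), flip = runif(1) < 0.5))
  list(patch = apply_dihedral(patch, tr$k, tr$flip),
       mask = apply_dihedral(mask, tr$k, tr$flip),
       k = tr$k, flip = tr$flip)
}
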