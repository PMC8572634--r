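#' Dice coefficient between two binary masks
#'
#' `DC = 2|P ∩ T| / (|P| + |T|)` where `P` is the predicted and `T` the
#' reference (ground-truth) mask. 1 means perfect overlap, 0 no overlap.
#' Two empty masks score 1 by convention (nothing to find, nothing found).
#'
#' @param pred,truth binary [volume()]s (or plain arrays) on the same grid.
#' @return An object of class `cow_seg_score`: `dice`, `n_pred`, `n_truth`,
#'   `n_overlap`.
#' @examples
#' a <- array(0L, c(4, 4, 1)); b <- a
#' a[1:2, 1, 1] <- 1L; b[2:3, 1, 1] <- 1L
#' dice_coefficient(a, b)$dice  # 2*1/(2+2) = 0.5
#' @export
dice_coefficient <- function(pred, truth) {
  pa <- if (is_volume(pred)) pred$data else pred
  ta <- if (is_volume(truth)) truth$data else truth
  if (!identical(dim(pa), dim(ta)))
    stop("masks are on different grids")
  if (is_volume(pred) && is_volume(truth)) stopifnot_same_grid(pred, truth)
  p <- pa != 0
  t <- ta != 0
  np <- sum(p); nt <- sum(t); no <- sum(p & t)
  dice <- if (np + nt == 0) 1 else 2 * no / (np + nt)
  structure(list(dice = dice, n_pred = np, n_truth = nt, n_overlap = no),
            class = "cow_seg_score")
}

#' @export
print.cow_seg_score <- function(x, ...) {
  cat(sprintf("<cow_seg_score> DC = %.4f (|P| = %d, |T| = %d, overlap = %d)\n",
              x$dice, x$n_pred, x$n_truth, x$n_overlap))
  invisible(x)
}

# is `segment` called "present" in a predicted mask?  A mechanical surrogate
# for expert visual review: sample points along the ground-truth centreline
# and call the segment present if at least `min_cover` of them fall inside
# the predicted mask dilated by one voxel. Sample points whose 1-voxel
# neighbourhood contains ground-truth voxels of other segments are excluded,
# otherwise junctional bleed from thick neighbours (e.g. the carotid
# terminus at the Pco origin) would mark even absent segments as covered.
segment_called_present <- function(pred_mask, phantom, segment,
                                   min_cover = 0.5) {
  seg <- phantom$tree[[segment]]
  if (is.null(seg)) stop("unknown segment name: ", segment)
  pts <- seg$centerline
  keep <- round(seq(1, nrow(pts), length.out = min(25L, nrow(pts))))
  pts <- pts[keep, , drop = FALSE]
  gt_dim <- dim(phantom$mask$data)
  gt_sp <- phantom$mask$spacing_mm
  others <- array(FALSE, gt_dim)
  for (nm in names(phantom$segment_voxels)) {
    if (identical(nm, segment)) next
    others[phantom$segment_voxels[[nm]]] <- TRUE
  }
  eligible <- vapply(seq_len(nrow(pts)), function(t) {
    idx <- round(pts[t, ] / gt_sp) + 1
    rng <- lapply(1:3, function(a)
      max(1L, idx[a] - 1L):min(gt_dim[a], idx[a] + 1L))
    !any(others[rng[[1]], rng[[2]], rng[[3]]])
  }, logical(1))
  if (sum(eligible) >= 3L) pts <- pts[eligible, , drop = FALSE]
  m <- if (is_volume(pred_mask)) pred_mask$data else pred_mask
  d <- dim(m)
  sp <- if (is_volume(pred_mask)) pred_mask$spacing_mm else phantom$mask$spacing_mm
  hit <- vapply(seq_len(nrow(pts)), function(t) {
    idx <- round(pts[t, ] / sp) + 1          # nearest voxel, 1-based
    rng <- lapply(1:3, function(a)
      max(1L, idx[a] - 1L):min(d[a], idx[a] + 1L))
    any(m[rng[[1]], rng[[2]], rng[[3]]] != 0)
  }, logical(1))
  mean(hit) >= min_cover
}

#' Per-segment detection accuracy over a cohort
#'
#' For each phantom, a Circle-of-Willis segment is called "present" in the
#' predicted mask if at least 50% of sample points along its ground-truth
#' centreline fall inside the prediction dilated by one voxel; sample
#' points whose neighbourhood contains ground-truth voxels of another
#' segment are excluded, so thick neighbours at junctions cannot stand in
#' for the segment itself.
#' The call is compared with the generative status (present = not absent).
#' The returned
#' accuracy is the fraction of phantoms where the call matches the truth.
#' This mechanical rule stands in for expert visual review of per-segment
#' segmentation success, which is not reproducible in code.
#'
#' @param predictions list of binary masks ([volume()]s), aligned with
#'   `phantoms`.
#' @param phantoms list of [generate_phantom()] objects.
#' @param segment a segment name from [cow_segment_names()], or a bare name
#'   like `"P1"` meaning both sides (each side scored separately).
#' @param min_cover fraction of centreline points required (default 0.5).
#' @return fraction in \[0, 1\].
#' @export
segment_detection_accuracy <- function(predictions, phantoms, segment,
                                       min_cover = 0.5) {
  if (length(predictions) != length(phantoms))
    stop("`predictions` and `phantoms` must be aligned lists")
  segs <- if (segment %in% COW_SEGMENTS) segment
          else if (paste0(segment, "_L") %in% COW_SEGMENTS)
            paste0(segment, c("_L", "_R"))
          else stop("unknown segment name: ", segment)
  ok <- 0L; tot <- 0L
  for (i in seq_along(phantoms)) {
    for (sg in segs) {
      truth_present <- phantoms[[i]]$spec$segment_statuses[[sg]] != "absent"
      call_present <- segment_called_present(predictions[[i]], phantoms[[i]],
                                             sg, min_cover)
      ok <- ok + (truth_present == call_present)
      tot <- tot + 1L
    }
  }
  ok / tot
}

#' Per-case evaluation report for a cohort
#'
#' @param predictions list of binary masks.
#' @param phantoms list of phantoms with ground-truth masks.
#' @return data.frame with one row per case: `case`, `dice`, voxel counts.
#' @export
evaluate_cohort <- function(predictions, phantoms) {
  rows <- lapply(seq_along(phantoms), function(i) {
    sc <- dice_coefficient(predictions[[i]], phantoms[[i]]$mask)
    data.frame(case = i, dice = sc$dice, n_pred = sc$n_pred,
               n_truth = sc$n_truth, n_overlap = sc$n_overlap)
  })
  do.call(rbind, rows)
}
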