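#' Specification of a synthetic head-neck CTA phantom
#'
#' Defines the geometry, per-segment status, focal stenoses, intensity model
#' and noise of one synthetic CTA-like volume with an exact vessel ground
#' truth. Intensities follow the HU scale: air far below 0, soft tissue a few
#' tens, contrast-enhanced vessels several hundreds, bone above 1000. The
#' phantom carries a full Circle of Willis (2 ICA, BA, 2 VA, 2 A1, Aco,
#' 2 P1, 2 Pco, 2 M1) plus short postcommunicating ACA/PCA stubs.
#'
#' Segment statuses: `"normal"`, `"hypoplastic"` (radius shrunk to 25% of the
#' contralateral homologue, i.e. more than 70% thinner, so it is
#' unambiguously a "variation" under the diameter rule), or `"absent"`
#' (rasterises to nothing). A stenosis `(segment, position, severity_pct)`
#' reduces the local radius to `(1 - severity/100)` of nominal over a short
#' plateau with smooth cosine shoulders.
#'
#' @param volume_shape integer length-3 voxel grid shape.
#' @param spacing_mm voxel spacing in mm (length 1 or 3).
#' @param segment_statuses named character vector/list, names from
#'   [cow_segment_names()]; unnamed segments default to `"normal"`.
#' @param base_radii_mm named numeric, default [cow_base_radii()].
#' @param stenoses list of `list(segment=, position=, severity_pct=)` with
#'   `position` in \[0, 1\] along the centreline and `severity_pct` in
#'   \[0, 100).
#' @param vessel_hu,tissue_hu,bone_hu,air_hu mean class intensities (HU).
#' @param noise_sd additive Gaussian noise standard deviation (HU).
#' @param bias_field_amplitude peak fractional deviation of the smooth
#'   multiplicative low-order polynomial bias field (0 disables it).
#' @param seed integer RNG seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `cow_phantom_spec`.
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
phantom_spec <- function(volume_shape = c(128L, 128L, 128L),
                         spacing_mm = 0.5,
                         segment_statuses = NULL,
                         base_radii_mm = cow_base_radii(),
                         stenoses = list(),
                         vessel_hu = 350, tissue_hu = 40,
                         bone_hu = 1200, air_hu = -1000,
                         noise_sd = 20, bias_field_amplitude = 0.1,
                         seed = 1L) {
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 8L))
    stop("`volume_shape` must be 3 integers >= 8")
  statuses <- setNames(rep("normal", length(COW_SEGMENTS)), COW_SEGMENTS)
  if (!is.null(segment_statuses)) {
    segment_statuses <- unlist(segment_statuses)
    bad <- setdiff(names(segment_statuses), COW_SEGMENTS)
    if (length(bad)) stop("unknown segment(s): ", paste(bad, collapse = ", "))
    if (!all(segment_statuses %in% c("normal", "hypoplastic", "absent")))
      stop("statuses must be normal/hypoplastic/absent")
    statuses[names(segment_statuses)] <- segment_statuses
  }
  base_radii_mm <- unlist(base_radii_mm)
  miss <- setdiff(COW_SEGMENTS, names(base_radii_mm))
  if (length(miss)) stop("base_radii_mm missing: ", paste(miss, collapse = ", "))
  if (any(base_radii_mm[COW_SEGMENTS] <= 0))
    stop("base radii must be strictly positive")
  for (st in stenoses) {
    if (!all(c("segment", "position", "severity_pct") %in% names(st)))
      stop("each stenosis needs segment, position, severity_pct")
    if (!st$segment %in% COW_SEGMENTS) stop("unknown segment: ", st$segment)
    if (st$position < 0 || st$position > 1) stop("stenosis position outside [0, 1]")
    if (st$severity_pct < 0 || st$severity_pct >= 100)
      stop("severity_pct must lie in [0, 100)")
  }
  structure(
    list(volume_shape = volume_shape, spacing_mm = as.numeric(spacing_mm),
         segment_statuses = statuses,
         base_radii_mm = base_radii_mm[COW_SEGMENTS],
         stenoses = stenoses, vessel_hu = vessel_hu, tissue_hu = tissue_hu,
         bone_hu = bone_hu, air_hu = air_hu, noise_sd = noise_sd,
         bias_field_amplitude = bias_field_amplitude, seed = as.integer(seed)),
    class = "cow_phantom_spec"
  )
}

# effective radius per segment after hypoplasia scaling
effective_radius <- function(spec, segment) {
  r <- spec$base_radii_mm[[segment]]
  if (spec$segment_statuses[[segment]] == "hypoplastic") {
    contra <- cow_homologue(segment)
    ref <- if (!is.na(contra)) spec$base_radii_mm[[contra]] else r
    r <- 0.25 * ref
  }
  r
}

# radius profile along a sampled centreline, with stenotic dips
radius_profile_for <- function(spec, segment, arclength, total_length) {
  r0 <- effective_radius(spec, segment)
  r <- rep(r0, length(arclength))
  for (st in spec$stenoses) {
    if (st$segment != segment) next
    centre <- st$position * total_length
    # The tube is rasterised as a union of spheres, so shoulder spheres bulge
    # into a too-short throat: the plateau must exceed the nominal radius for
    # the rendered lumen to reach (1 - severity) * r0.
    plateau <- max(2.5 * r0, 2.0)   # mm at full severity
    ramp <- 2.0                     # mm cosine shoulders
    d <- abs(arclength - centre)
    f <- ifelse(d <= plateau / 2, 1,
                ifelse(d >= plateau / 2 + ramp, 0,
                       0.5 * (1 + cos(pi * (d - plateau / 2) / ramp))))
    r <- r * (1 - st$severity_pct / 100 * f)
  }
  r
}

#' Generate one synthetic CTA phantom
#'
#' Builds the vessel tree from the spec, rasterises every non-absent segment
#' with sub-voxel partial-volume sampling (supersampling factor 3 per axis),
#' composes the background (soft tissue inside the head, a cranial bone
#' shell, air outside), applies a smooth multiplicative bias field and
#' additive Gaussian noise, and returns the volume together with the exact
#' binary vessel mask (a voxel is foreground iff its centre lies within the
#' local radius of some non-absent segment's centreline).
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `cow_phantom`: list with `volume` and `mask`
#'   ([volume()]s on the same grid), `tree` (per-segment centreline, radius
#'   profile and status), `config` (the variant statuses of the seven
#'   ring segments used by the statistics stage), `anatomy` (head geometry)
#'   and `spec`.
#' @examples
#' p <- generate_phantom(phantom_spec(volume_shape = c(48, 48, 48),
#'                                    spacing_mm = 1.4, noise_sd = 0))
#' sum(p$mask$data)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "cow_phantom_spec"))
  shp <- spec$volume_shape
  sp <- spec$spacing_mm
  extent <- shp * sp
  wp <- cow_waypoints(extent)

  # sizing check: radii are absolute mm while the geometry scales with the
  # volume, so below ~32 mm of physical extent neighbouring vessels collide
  # and the tree cannot be contained meaningfully
  allpts <- do.call(rbind, wp)
  rmax <- max(spec$base_radii_mm)
  if (min(extent) < 32 ||
      any(apply(allpts, 2, min) - rmax < 0) ||
      any(apply(allpts, 2, max) + rmax > extent))
    stop("volume too small to contain the vessel tree (sizing error)")

  step <- 0.2 * min(sp)
  nvox <- prod(shp)
  occ <- numeric(nvox)
  mask <- logical(nvox)
  tree <- list()
  segment_voxels <- list()

  for (seg in COW_SEGMENTS) {
    status <- spec$segment_statuses[[seg]]
    cl <- sample_centerline(wp[[seg]], step)
    rp <- radius_profile_for(spec, seg, cl$arclength, cl$length)
    tree[[seg]] <- list(name = seg, centerline = cl$points,
                        arclength = cl$arclength,
                        radius_profile = if (status == "absent") rp * 0 else rp,
                        status = status)
    if (status == "absent") { segment_voxels[[seg]] <- integer(0); next }
    ras <- rasterize_tube_cpp(cl$points, rp, shp, sp, c(0, 0, 0), 3L)
    occ <- pmax(occ, ras$occ)
    segment_voxels[[seg]] <- which(ras$mask)
    mask <- mask | ras$mask
  }

  # background: air outside the head, soft tissue inside, bone vault shell
  centre <- c(extent[1] / 2, extent[2] / 2, 0.625 * extent[3])
  scl <- min(extent) / 64
  xs <- (seq_len(shp[1]) - 1) * sp[1]
  ys <- (seq_len(shp[2]) - 1) * sp[2]
  zs <- (seq_len(shp[3]) - 1) * sp[3]
  dx2 <- (xs - centre[1])^2
  dy2 <- (ys - centre[2])^2
  dz2 <- (zs - centre[3])^2
  dist <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  head_r <- 0.48 * min(extent)
  skull_r <- 20 * scl
  skull_half_th <- 1.5 * scl
  zmask <- rep(rep(zs >= centre[3] - 2 * scl, each = shp[1] * shp[2]), 1)
  bg <- ifelse(dist <= head_r, spec$tissue_hu, spec$air_hu)
  in_shell <- (abs(dist - skull_r) <= skull_half_th) & zmask
  bg[in_shell] <- spec$bone_hu

  img <- occ * spec$vessel_hu + (1 - occ) * as.numeric(bg)

  with_seed(spec$seed, {
    if (spec$bias_field_amplitude > 0) {
      u <- list(2 * xs / extent[1] - 1, 2 * ys / extent[2] - 1,
                2 * zs / extent[3] - 1)
      cf <- rnorm(9)
      q <- cf[1] * rep(u[[1]], times = shp[2] * shp[3]) +
           cf[2] * rep(rep(u[[2]], each = shp[1]), times = shp[3]) +
           cf[3] * rep(u[[3]], each = shp[1] * shp[2]) +
           cf[4] * rep(u[[1]]^2, times = shp[2] * shp[3]) +
           cf[5] * rep(rep(u[[2]]^2, each = shp[1]), times = shp[3]) +
           cf[6] * rep(u[[3]]^2, each = shp[1] * shp[2]) +
           cf[7] * rep(outer(u[[1]], u[[2]]), times = shp[3]) +
           cf[8] * rep(u[[1]], times = shp[2] * shp[3]) *
                   rep(u[[3]], each = shp[1] * shp[2]) +
           cf[9] * rep(rep(u[[2]], each = shp[1]), times = shp[3]) *
                   rep(u[[3]], each = shp[1] * shp[2])
      q <- q / max(abs(q))
      img <- img * (1 + spec$bias_field_amplitude * q)
    }
    if (spec$noise_sd > 0) img <- img + rnorm(nvox, 0, spec$noise_sd)
  })

  config <- cow_configuration(
    setNames(ifelse(spec$segment_statuses[COW_STAT_SEGMENTS] == "normal",
                    "normal", "variation"), COW_STAT_SEGMENTS))

  structure(
    list(volume = volume(array(img, shp), sp),
         mask = volume(array(as.integer(mask), shp), sp),
         tree = tree, segment_voxels = segment_voxels, config = config,
         anatomy = list(centre = centre, head_r = head_r, skull_r = skull_r,
                        skull_half_th = skull_half_th, scale = scl),
         spec = spec),
    class = "cow_phantom"
  )
}

#' @export
print.cow_phantom <- function(x, ...) {
  nv <- sum(x$mask$data)
  var <- names(x$spec$segment_statuses)[x$spec$segment_statuses != "normal"]
  cat(sprintf("<cow_phantom> %s voxels, %d vessel voxels%s\n",
              paste(dim(x$volume$data), collapse = "x"), nv,
              if (length(var)) paste0(", variants: ", paste(var, collapse = ", "))
              else ""))
  invisible(x)
}

#' Generate a cohort of phantoms with random variants and stenoses
#'
#' Draws per-segment statuses independently per phantom: with probability
#' `variation_freqs[segment]` the segment is a variant — hypoplastic with
#' probability `hypoplasia_share`, absent otherwise — else normal. Bare
#' segment names without a
#' side suffix (e.g. `"Pco"`) are expanded to both sides, each drawn
#' independently. `stenosis_freqs` likewise gives the probability of
#' inserting one focal stenosis on a segment (severity drawn uniformly from
#' 30-90%, position from 0.3-0.7).
#'
#' @param n number of phantoms (> 0).
#' @param variation_freqs named probabilities in \[0, 1\].
#' @param stenosis_freqs named probabilities in \[0, 1\].
#' @param seed master seed; each phantom receives a derived child seed.
#' @param base_spec a [phantom_spec()] used as template for geometry,
#'   intensities and noise.
#' @param hypoplasia_share probability that a drawn variant is hypoplastic
#'   rather than absent (default 0.5; 0 gives absence-only cohorts, useful
#'   when presence/absence detection is the quantity under study).
#' @return list of `cow_phantom` objects.
#' @export
generate_cohort <- function(n, variation_freqs = NULL, stenosis_freqs = NULL,
                            seed = 1L, base_spec = phantom_spec(),
                            hypoplasia_share = 0.5) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0)
    stop("`n` must be a positive count")
  n <- as.integer(n)
  expand_sides <- function(freqs) {
    if (is.null(freqs)) return(numeric(0))
    freqs <- unlist(freqs)
    out <- numeric(0)
    for (nm in names(freqs)) {
      if (nm %in% COW_SEGMENTS) out[nm] <- freqs[[nm]]
      else if (paste0(nm, "_L") %in% COW_SEGMENTS) {
        out[paste0(nm, "_L")] <- freqs[[nm]]
        out[paste0(nm, "_R")] <- freqs[[nm]]
      } else stop("unknown segment in frequency map: ", nm)
    }
    if (any(out < 0 | out > 1)) stop("probabilities must lie in [0, 1]")
    out
  }
  vf <- expand_sides(variation_freqs)
  sf <- expand_sides(stenosis_freqs)
  seeds <- derive_seeds(seed, 3L * n)
  lapply(seq_len(n), function(i) {
    statuses <- with_seed(seeds[3 * i - 2], {
      st <- setNames(rep("normal", length(vf)), names(vf))
      for (nm in names(vf))
        if (runif(1) < vf[[nm]])
          st[nm] <- if (runif(1) < hypoplasia_share) "hypoplastic" else "absent"
      st
    })
    stenoses <- with_seed(seeds[3 * i - 1], {
      out <- list()
      for (nm in names(sf)) {
        hit <- runif(1) < sf[[nm]]
        absent <- !is.na(statuses[nm]) && identical(unname(statuses[nm]), "absent")
        if (hit && !absent)
          out[[length(out) + 1L]] <- list(segment = nm,
                                          position = runif(1, 0.3, 0.7),
                                          severity_pct = runif(1, 30, 90))
      }
      out
    })
    spec <- base_spec
    spec$segment_statuses[names(statuses)] <- statuses
    spec$stenoses <- c(base_spec$stenoses, stenoses)
    spec$seed <- seeds[3 * i]
    generate_phantom(spec)
  })
}

#' Ground-truth configuration table for a cohort
#'
#' One row per phantom, one column per segment status — the generative truth
#' against which classification and detection are evaluated.
#'
#' @param cohort list of `cow_phantom`.
#' @return data.frame with columns `phantom` and one per segment.
#' @export
cohort_truth_table <- function(cohort) {
  rows <- lapply(seq_along(cohort), function(i) {
    st <- cohort[[i]]$spec$segment_statuses
    c(list(phantom = i), as.list(st))
  })
  do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
}

#' Read and write phantom specs as YAML
#'
#' @param spec a [phantom_spec()]; `path` a file path.
#' @return `read_phantom_spec()` returns a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  x <- unclass(spec)
  x$segment_statuses <- as.list(x$segment_statuses)
  x$base_radii_mm <- as.list(x$base_radii_mm)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(phantom_spec, x)
}
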