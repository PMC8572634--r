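# Hand-designed Circle-of-Willis geometry.
#
# Waypoints are expressed in mm relative to the centre of the arterial ring,
# for a reference head extent of 64 mm, and are scaled linearly to the
# physical extent of the requested volume. Axes: x = left-right (+x left),
# y = posterior-anterior (+y anterior), z = inferior-superior (+z cranial).
# Only the topology matters for segmentation/classification experiments;
# no claim of anatomical shape fidelity is made.

COW_SEGMENTS <- c(
  "ICA_L", "ICA_R", "BA", "VA_L", "VA_R",
  "A1_L", "A1_R", "Aco", "P1_L", "P1_R",
  "Pco_L", "Pco_R", "M1_L", "M1_R",
  "pACA_L", "pACA_R", "pPCA_L", "pPCA_R"
)

# segments entering the variant/completeness statistics
COW_STAT_SEGMENTS <- c("Aco", "A1_L", "A1_R", "Pco_L", "Pco_R", "P1_L", "P1_R")

#' Circle-of-Willis segment names and default radii
#'
#' `cow_segment_names()` lists the modelled arterial segments; left/right
#' homologues carry `_L`/`_R` suffixes. `cow_base_radii()` gives the default
#' lumen radius (mm) per segment: the anterior communicating artery (Aco) is
#' deliberately the thinnest segment of the ring, which makes it the hardest
#' to segment and detect — thin vessels are where automated CoW assessment
#' degrades first.
#'
#' @return A character vector, or a named numeric vector of radii in mm.
#' @export
cow_segment_names <- function() COW_SEGMENTS

#' @rdname cow_segment_names
#' @export
cow_base_radii <- function() {
  c(ICA_L = 2.4, ICA_R = 2.4, BA = 1.8, VA_L = 1.4, VA_R = 1.4,
    A1_L = 1.1, A1_R = 1.1, Aco = 0.5, P1_L = 1.1, P1_R = 1.1,
    Pco_L = 0.7, Pco_R = 0.7, M1_L = 1.5, M1_R = 1.5,
    pACA_L = 0.9, pACA_R = 0.9, pPCA_L = 0.9, pPCA_R = 0.9)
}

# contralateral homologue (NA for midline vessels)
cow_homologue <- function(segment) {
  if (grepl("_L$", segment)) sub("_L$", "_R", segment)
  else if (grepl("_R$", segment)) sub("_R$", "_L", segment)
  else NA_character_
}

# Waypoints relative to the ring centre for a 64 mm reference extent.
cow_waypoints_ref <- function() {
  mirror <- function(m) { m[, 1] <- -m[, 1]; m }
  w <- list(
    ICA_L = rbind(c(9, -2, -28), c(8.5, 0, -18), c(7.5, 3, -8),
                  c(7.2, 2.5, -2), c(7, 2, 0)),
    VA_L  = rbind(c(3.5, -10, -28), c(2.5, -10.5, -18), c(1.2, -10, -11),
                  c(0.3, -9.6, -8.5)),
    BA    = rbind(c(0, -9.5, -8), c(0, -9, -4), c(0, -8, -1)),
    P1_L  = rbind(c(0, -8, -1), c(3, -6.5, -0.5), c(6, -5, 0)),
    Pco_L = rbind(c(7, 2, 0), c(6.8, -1.5, 0), c(6, -5, 0)),
    M1_L  = rbind(c(7, 2, 0), c(10.5, 1.5, 0), c(14, 1, 0)),
    A1_L  = rbind(c(7, 2, 0), c(5.5, 5.5, 0.5), c(4, 8.5, 1)),
    Aco   = rbind(c(4, 8.5, 1), c(0, 9.2, 1), c(-4, 8.5, 1)),
    pACA_L = rbind(c(4, 8.5, 1), c(3.6, 10, 3.5), c(3.2, 11, 6)),
    pPCA_L = rbind(c(6, -5, 0), c(8, -7, 2), c(10, -8.5, 4))
  )
  for (nm in c("ICA_L", "VA_L", "P1_L", "Pco_L", "M1_L", "A1_L",
               "pACA_L", "pPCA_L"))
    w[[sub("_L$", "_R", nm)]] <- mirror(w[[nm]])
  w[COW_SEGMENTS]
}

# Scale reference waypoints to a volume of physical extent `extent_mm`
# (length 3) and return world-coordinate waypoints per segment. The ring
# centre is placed at the x-y centre, 62.5% of the way up the z extent.
cow_waypoints <- function(extent_mm) {
  s <- min(extent_mm) / 64
  centre <- c(extent_mm[1] / 2, extent_mm[2] / 2, 0.625 * extent_mm[3])
  lapply(cow_waypoints_ref(), function(m) {
    sweep(m * s, 2, centre, "+")
  })
}

# Piecewise-cubic centreline through waypoints, sampled at `step_mm` arclength
# spacing (natural cubic spline per coordinate over cumulative chord length).
sample_centerline <- function(waypoints, step_mm) {
  d <- sqrt(rowSums(diff(waypoints)^2))
  tt <- c(0, cumsum(d))
  len <- tt[length(tt)]
  n <- max(2L, ceiling(len / step_mm) + 1L)
  ts <- seq(0, len, length.out = n)
  if (nrow(waypoints) < 3) {
    pts <- sapply(1:3, function(a)
      approx(tt, waypoints[, a], xout = ts)$y)
  } else {
    pts <- sapply(1:3, function(a)
      splinefun(tt, waypoints[, a], method = "natural")(ts))
  }
  list(points = pts, arclength = ts, length = len)
}

# Unit tangents of a sampled centreline by central differences.
centerline_tangents <- function(pts) {
  n <- nrow(pts)
  tg <- (pts[c(2:n, n), ] - pts[c(1, 1:(n - 1)), ])
  nrm <- sqrt(rowSums(tg^2))
  nrm[nrm == 0] <- 1
  tg / nrm
}
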