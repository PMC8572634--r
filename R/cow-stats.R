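#' Variant configuration of the Circle of Willis
#'
#' Status (`"normal"` / `"variation"`) of the seven ring segments that enter
#' the completeness definition: the anterior communicating artery (Aco),
#' both precommunicating anterior cerebral segments (A1), both posterior
#' communicating arteries (Pco) and both precommunicating posterior cerebral
#' segments (P1). `aco_fused_flag` records the special case of bilateral
#' ACAs running fused, in which a non-visualised Aco still counts as normal.
#'
#' @param statuses named character vector over
#'   `Aco, A1_L, A1_R, Pco_L, Pco_R, P1_L, P1_R` with values `"normal"` or
#'   `"variation"`.
#' @param aco_fused_flag logical.
#' @return An object of class `cow_configuration`.
#' @export
cow_configuration <- function(statuses, aco_fused_flag = FALSE) {
  statuses <- unlist(statuses)
  if (!setequal(names(statuses), COW_STAT_SEGMENTS))
    stop("statuses must cover exactly: ",
         paste(COW_STAT_SEGMENTS, collapse = ", "))
  if (!all(statuses %in% c("normal", "variation")))
    stop("statuses must be 'normal' or 'variation'")
  structure(list(statuses = statuses[COW_STAT_SEGMENTS],
                 aco_fused_flag = isTRUE(aco_fused_flag)),
            class = "cow_configuration")
}

#' Classify one CoW segment as normal or variation
#'
#' A segment is a "variation" if it is not visualised, or if its diameter is
#' more than 70% thinner than the contralateral homologue (i.e. diameter
#' strictly below 0.3 times the contralateral diameter — the operational
#' hypoplasia rule for A1, P1 and Pco). An Aco with the bilateral ACAs
#' fused is classified normal regardless of visualisation.
#'
#' @param diameter segment diameter in mm (ignored if not visualised).
#' @param contralateral_diameter contralateral diameter in mm, or `NULL` for
#'   midline segments.
#' @param visualized was the segment visualised at all?
#' @param fused fused bilateral ACA flag (only meaningful for Aco).
#' @return `"normal"` or `"variation"`.
#' @examples
#' classify_segment(2.0, 2.1, visualized = TRUE)            # normal
#' classify_segment(0.25, 1.0, visualized = TRUE)           # variation
#' classify_segment(0, NULL, visualized = FALSE, fused = TRUE)  # normal (Aco)
#' @export
classify_segment <- function(diameter, contralateral_diameter = NULL,
                             visualized = TRUE, fused = FALSE) {
  if (!is.null(diameter) && !is.na(diameter) && diameter < 0)
    stop("negative diameter")
  if (!is.null(contralateral_diameter) && !is.na(contralateral_diameter) &&
      contralateral_diameter < 0)
    stop("negative diameter")
  if (isTRUE(fused)) return("normal")
  if (!isTRUE(visualized)) return("variation")
  if (!is.null(contralateral_diameter) && !is.na(contralateral_diameter) &&
      diameter < 0.3 * contralateral_diameter)
    return("variation")
  "normal"
}

#' Completeness of the Circle of Willis
#'
#' The anterior part is complete iff Aco and both A1 are normal; the
#' posterior part iff both Pco and both P1 are normal; the entire circle
#' iff both parts are complete.
#'
#' @param cfg a [cow_configuration()].
#' @return list of logicals `entire`, `anterior`, `posterior` (TRUE =
#'   complete).
#' @export
classify_completeness <- function(cfg) {
  stopifnot(inherits(cfg, "cow_configuration"))
  st <- cfg$statuses
  anterior <- all(st[c("Aco", "A1_L", "A1_R")] == "normal")
  posterior <- all(st[c("Pco_L", "Pco_R", "P1_L", "P1_R")] == "normal")
  list(entire = anterior && posterior, anterior = anterior,
       posterior = posterior)
}

#' NASCET stenosis grading
#'
#' Bands: 0% normal; up to 29% mild; 30-69% moderate; 70% and above severe.
#' Fractional percentages between the printed band edges (29, 30) are
#' rounded to the nearest integer before banding.
#'
#' @param pct stenosis percentage in \[0, 100\].
#' @return An object of class `cow_stenosis_grade`: `pct` and `grade`
#'   (factor normal/mild/moderate/severe).
#' @export
grade_stenosis <- function(pct) {
  if (!is.numeric(pct) || is.na(pct) || pct < 0 || pct > 100)
    stop("stenosis percentage must lie in [0, 100]")
  p <- if (pct > 29 && pct < 30) round(pct) else pct
  grade <- if (p == 0) "normal"
           else if (p <= 29) "mild"
           else if (p < 70) "moderate"
           else "severe"
  structure(list(pct = pct,
                 grade = factor(grade, levels = c("normal", "mild",
                                                  "moderate", "severe"))),
            class = "cow_stenosis_grade")
}

#' Measure stenosis severity from a binary mask along a known centreline
#'
#' Estimates the lumen diameter profile from cross-sectional areas in thin
#' slabs perpendicular to the centreline (`d = 2 * sqrt(A / pi)`), then
#' reports `100 * (1 - d_min / d_ref)` with the reference diameter taken as
#' the median profile diameter (a robust surrogate for the NASCET distal
#' reference). Samples within 15% of either end are excluded so junction
#' voxels of connected segments do not bias the profile.
#'
#' @param mask binary [volume()].
#' @param segment one element of a phantom's `tree` (needs `centerline`,
#'   `radius_profile`, `status`).
#' @return percentage in \[0, 100\]; 100 if the mask is empty over the
#'   segment (occlusion).
#' @export
measure_stenosis_pct <- function(mask, segment) {
  stopifnot(is_volume(mask))
  if (identical(segment$status, "absent"))
    stop("cannot measure stenosis on an absent segment")
  pts <- segment$centerline
  n <- nrow(pts)
  keep <- seq_len(n) > 0.15 * n & seq_len(n) <= 0.85 * n
  pts <- pts[keep, , drop = FALSE]
  tg <- centerline_tangents(segment$centerline)[keep, , drop = FALSE]
  rmax <- max(segment$radius_profile)
  sp <- mask$spacing_mm
  areas <- tube_profile_cpp(as.logical(mask$data != 0), dim(mask$data), sp,
                            mask$origin_mm, pts, tg,
                            window_r = rmax + 2 * max(sp),
                            slab_half = 0.75 * max(sp))
  areas <- areas[is.finite(areas)]
  if (!length(areas) || max(areas) <= 0) return(100)
  diam <- 2 * sqrt(areas / pi)
  # moving-average over ~±0.5 mm to suppress voxel-quantisation jitter in the
  # slab counts before taking the minimum
  step <- if (length(segment$arclength) > 1) diff(segment$arclength[1:2])
          else max(sp)
  w <- max(1L, round(0.5 / step))
  if (length(diam) > 2 * w) {
    kern <- rep(1 / (2 * w + 1), 2 * w + 1)
    sm <- stats::filter(diam, kern, sides = 2)
    diam <- sm[!is.na(sm)]
  }
  dref <- median(diam)
  if (dref <= 0) return(100)
  max(0, min(100, 100 * (1 - min(diam) / dref)))
}

#' Classify a phantom's ring segments from ground-truth geometry
#'
#' Applies [classify_segment()] to the generative truth. A segment counts as
#' visualised iff it is traceable along its course — it rasterised at least
#' one voxel per two millimetres of centreline length — *and* its lumen is
#' at least one voxel wide: a vessel thinner than the voxel size occupies
#' only a small fraction of any voxel it touches and is lost to partial
#' volume, so a sub-resolution hypoplastic segment that leaves a dotted
#' line of stray voxels is not "visualised" in any radiological sense.
#' Diameters are the nominal
#' (peak) profile diameters, so a focal stenosis on a normal segment does
#' not masquerade as hypoplasia; A1/P1/Pco use the contralateral diameter
#' for the 70%-thinner rule.
#'
#' @param phantom a [generate_phantom()] object.
#' @return A [cow_configuration()].
#' @export
classify_phantom <- function(phantom) {
  st <- setNames(character(length(COW_STAT_SEGMENTS)), COW_STAT_SEGMENTS)
  for (seg in COW_STAT_SEGMENTS) {
    len <- max(phantom$tree[[seg]]$arclength)
    nominal_diam <- 2 * max(phantom$tree[[seg]]$radius_profile)
    visualized <- length(phantom$segment_voxels[[seg]]) >= len / 2 &&
      nominal_diam >= min(phantom$mask$spacing_mm)
    diam <- if (visualized) nominal_diam else 0
    contra <- cow_homologue(seg)
    cdiam <- NULL
    if (!is.na(contra) && length(phantom$segment_voxels[[contra]]) > 0)
      cdiam <- 2 * max(phantom$tree[[contra]]$radius_profile)
    st[seg] <- classify_segment(diam, cdiam, visualized)
  }
  cow_configuration(st)
}

#' Reconstruct an event count from a printed (n, %) summary
#'
#' Prevalence tables print group size and integer percentages; the
#' underlying count is recovered as `n * pct / 100` rounded half-up (the
#' convention print tables use; banker's rounding would mis-invert x.5
#' percentages). A warning is emitted if the recovered count does not
#' re-round to the printed percentage.
#'
#' @param n group size.
#' @param pct printed percentage in \[0, 100\].
#' @return integer count.
#' @examples
#' reconstruct_counts(53, 36)  # 19
#' reconstruct_counts(27, 59)  # 16
#' @export
reconstruct_counts <- function(n, pct) {
  if (pct < 0 || pct > 100) stop("pct must lie in [0, 100]")
  half_up <- function(x) floor(x + 0.5)
  k <- half_up(n * pct / 100)
  if (half_up(100 * k / n) != half_up(pct))
    warning(sprintf("count %d/%d re-rounds to %d%%, not the printed %g%%",
                    k, n, round(100 * k / n), pct))
  as.integer(k)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with 1
#' degree of freedom, two-sided, no multiple-comparison correction — the
#' convention under which the prevalence comparisons here are computed.
#'
#' @param t 2x2 matrix of nonnegative integer counts
#'   (group x event/non-event).
#' @return list with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_test(rbind(c(19, 34), c(16, 11)))$p_value  # ~0.046
#' @export
chi_square_test <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == 2L)) stop("`t` must be a 2x2 table")
  if (any(t < 0) || any(t != round(t))) stop("counts must be nonnegative integers")
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    stop("chi-square statistic undefined: a table margin is zero")
  ht <- suppressWarnings(chisq.test(t, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Two-sample t-test from summary statistics
#'
#' Two-sided t-test computed from (mean, sd, n) per group, as needed when
#' only printed summaries are available. Pooled-variance by default;
#' `welch = TRUE` uses the Welch-Satterthwaite form.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (`n >= 2`, `sd >= 0`).
#' @param welch use Welch's unequal-variance form.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
t_test_two_sample <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) return(list(statistic = 0, df = n1 + n2 - 2, p_value = 1))
    stop("degenerate: zero variance in both groups with unequal means")
  }
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    stat <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(statistic = stat, df = df, p_value = 2 * pt(-abs(stat), df))
}

#' Published prevalence summary table of CoW variants by group
#'
#' The group summaries (group size, age, sex, and per-patient prevalence
#' percentages of variation in Aco/A1/Pco/P1 and of incompleteness of the
#' entire, anterior and posterior circle) for the eight study groups: young
#' normal (Yn), senior normal (Sn), male, female, mild-moderate afferent
#' stenosis (AMs), severe afferent stenosis (ASs), severe efferent stenosis
#' (ESs) and its control (Ec). Bilateral segments are summarised per patient
#' (variation on either side).
#'
#' @return data.frame, one row per group.
#' @export
cow_table2 <- function() {
  data.frame(
    group = c("Yn", "Sn", "Male", "Female", "AMs", "ASs", "ESs", "Ec"),
    block = c(1, 1, 2, 2, 3, 3, 4, 4),
    n = c(53, 27, 40, 40, 41, 27, 50, 65),
    age_mean = c(30, 63, 42, 48, 66, 67, 51, 53),
    age_sd = c(4, 5, 15, 15, 6, 9, 13, 16),
    male_pct = c(68, 48, 100, 0, 61, 74, 78, 68),
    Aco = c(36, 59, 30, 55, 49, 48, 32, 40),
    A1 = c(11, 22, 10, 18, 12, 22, 24, 17),
    Pco = c(85, 96, 93, 90, 95, 93, 88, 86),
    P1 = c(25, 15, 18, 23, 10, 19, 8, 20),
    entire_incomplete = c(98, 100, 100, 95, 98, 100, 94, 97),
    anterior_incomplete = c(47, 78, 40, 63, 61, 67, 52, 56),
    posterior_incomplete = c(96, 96, 98, 93, 98, 96, 84, 94)
  )
}

#' Compare outcome prevalences between group pairs
#'
#' For each requested (pair, outcome): reconstruct event counts from the
#' printed (n, %) summaries, build the 2x2 table and run the uncorrected
#' chi-square test. A group compared with itself yields p = 1.
#'
#' @param rows data.frame like [cow_table2()]: columns `group`, `n`, and one
#'   percentage column per outcome.
#' @param outcomes character vector of outcome column names.
#' @param pairs list of length-2 character vectors of group names.
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `group1`, `group2`, `outcome`, `chi2`,
#'   `df`, `p`, `significant`.
#' @examples
#' res <- compare_groups(cow_table2(), "Aco", list(c("Yn", "Sn")))
#' round(res$p, 3)  # 0.046
#' @export
compare_groups <- function(rows, outcomes, pairs, alpha = 0.05) {
  out <- list()
  for (pr in pairs) {
    if (!all(pr %in% rows$group))
      stop("pair refers to unknown group(s): ", paste(pr, collapse = " vs "))
    r1 <- rows[rows$group == pr[1], ][1, ]
    r2 <- rows[rows$group == pr[2], ][1, ]
    for (oc in outcomes) {
      if (!oc %in% names(rows)) stop("unknown outcome column: ", oc)
      k1 <- reconstruct_counts(r1$n, r1[[oc]])
      k2 <- reconstruct_counts(r2$n, r2[[oc]])
      tab <- rbind(c(k1, r1$n - k1), c(k2, r2$n - k2))
      res <- if (identical(pr[1], pr[2]))
        list(statistic = 0, df = 1, p_value = 1)
      else chi_square_test(tab)
      out[[length(out) + 1L]] <- data.frame(
        group1 = pr[1], group2 = pr[2], outcome = oc,
        chi2 = res$statistic, df = res$df, p = res$p_value,
        significant = res$p_value < alpha)
    }
  }
  do.call(rbind, out)
}
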