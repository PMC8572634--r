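test_that("phantom generation is deterministic for a fixed seed", {
  s <- phantom_spec(volume_shape = c(48, 48, 48), spacing_mm = 4 / 3,
                    seed = 7L)
  p1 <- generate_phantom(s)
  p2 <- generate_phantom(s)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$mask$data, p2$mask$data)
})

test_that("mask agrees with the brute-force point-in-tube oracle", {
  p <- quiet_phantom(shape = 48L, spacing = 4 / 3)
  oracle <- brute_force_mask(p)
  expect_identical(p$mask$data == 1L, oracle)
  expect_gt(sum(oracle), 0)
})

test_that("absent segments contribute nothing; bilateral A1 stay disjoint", {
  p <- quiet_phantom(segment_statuses = list(Aco = "absent"))
  expect_length(p$segment_voxels$Aco, 0)
  expect_length(intersect(p$segment_voxels$A1_L, p$segment_voxels$A1_R), 0)
  # and with Aco present, its voxels disappear from the Aco-absent mask
  pfull <- quiet_phantom()
  expect_gt(length(pfull$segment_voxels$Aco), 0)
  aco_only <- setdiff(pfull$segment_voxels$Aco, unlist(p$segment_voxels))
  expect_gt(length(aco_only), 0)
  expect_true(all(p$mask$data[aco_only] == 0))
})

test_that("hypoplastic segments satisfy the 70%-thinner rule with margin", {
  p <- quiet_phantom(segment_statuses = list(Pco_L = "hypoplastic"))
  r_hypo <- max(p$tree$Pco_L$radius_profile)
  r_contra <- max(p$tree$Pco_R$radius_profile)
  expect_lte(r_hypo, 0.3 * r_contra)
  expect_gt(r_hypo, 0)
})

test_that("increasing stenosis severity never increases segment voxel count", {
  counts <- vapply(c(0, 30, 60, 90), function(sev) {
    stn <- if (sev == 0) list() else
      list(list(segment = "ICA_L", position = 0.5, severity_pct = sev))
    p <- generate_phantom(phantom_spec(volume_shape = c(64, 64, 64),
                                       spacing_mm = 1,
                                       segment_statuses = only_segments("ICA_L"),
                                       stenoses = stn, noise_sd = 0,
                                       bias_field_amplitude = 0, seed = 3L))
    length(p$segment_voxels$ICA_L)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[4])
})

test_that("noise-free intensity classes are ordered air < tissue < vessel < bone", {
  p <- quiet_phantom()
  img <- p$volume$data
  an <- p$anatomy
  d <- dim(img)
  sp <- p$volume$spacing_mm
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
  dist <- sqrt(outer(outer((ax[[1]] - an$centre[1])^2,
                           (ax[[2]] - an$centre[2])^2, "+"),
                     (ax[[3]] - an$centre[3])^2, "+"))
  vessel <- p$mask$data == 1
  bone <- abs(dist - an$skull_r) <= 0.5 * an$skull_half_th &
    rep(rep(ax[[3]] >= an$centre[3], each = d[1] * d[2]), 1) & !vessel
  air <- dist > an$head_r * 1.05
  tissue <- dist < 0.5 * an$skull_r & !vessel &
    abs(dist - an$skull_r) > an$skull_half_th
  means <- c(air = mean(img[air]), tissue = mean(img[tissue & !bone]),
             vessel = mean(img[vessel]), bone = mean(img[bone]))
  expect_true(all(diff(means) > 0))
})

test_that("a volume too small for the tree raises a sizing error", {
  expect_error(generate_phantom(phantom_spec(volume_shape = c(32, 32, 32),
                                             spacing_mm = 0.5)),
               "sizing")
})

test_that("spec validation rejects inconsistent inputs", {
  expect_error(phantom_spec(segment_statuses = list(XX_L = "absent")),
               "unknown segment")
  expect_error(phantom_spec(stenoses = list(list(segment = "BA",
                                                 position = 0.5,
                                                 severity_pct = 100))),
               "severity")
  expect_error(generate_cohort(0), "positive")
})

test_that("degenerate cohort probabilities behave as stated", {
  base <- phantom_spec(volume_shape = c(32, 32, 32), spacing_mm = 2,
                       noise_sd = 0, bias_field_amplitude = 0)
  all_zero <- generate_cohort(5, variation_freqs = list(Pco = 0, Aco = 0),
                              seed = 5L, base_spec = base)
  expect_true(all(vapply(all_zero, function(p)
    all(p$spec$segment_statuses == "normal"), logical(1))))
  all_one <- generate_cohort(5, variation_freqs = list(Aco = 1),
                             seed = 5L, base_spec = base)
  expect_true(all(vapply(all_one, function(p)
    p$spec$segment_statuses[["Aco"]] != "normal", logical(1))))
})

test_that("cohort truth table records one row per phantom, one column per segment", {
  base <- phantom_spec(volume_shape = c(32, 32, 32), spacing_mm = 2)
  co <- generate_cohort(4, variation_freqs = list(Pco = 0.5), seed = 2L,
                        base_spec = base)
  tt <- cohort_truth_table(co)
  expect_equal(nrow(tt), 4)
  expect_true(all(cow_segment_names() %in% names(tt)))
  expect_true(all(unlist(tt[cow_segment_names()]) %in%
                    c("normal", "hypoplastic", "absent")))
})

test_that("phantom specs survive a YAML round trip", {
  s <- phantom_spec(volume_shape = c(48, 48, 48), spacing_mm = 4 / 3,
                    segment_statuses = list(Aco = "absent"),
                    stenoses = list(list(segment = "BA", position = 0.4,
                                         severity_pct = 50)),
                    seed = 9L)
  f <- tempfile(fileext = ".yaml")
  write_phantom_spec(s, f)
  s2 <- read_phantom_spec(f)
  expect_equal(s2$segment_statuses, s$segment_statuses)
  expect_equal(s2$base_radii_mm, s$base_radii_mm)
  expect_equal(s2$stenoses[[1]]$severity_pct, 50)
  expect_identical(generate_phantom(s)$mask$data,
                   generate_phantom(s2)$mask$data)
})

test_that("volumes round-trip through NIfTI with spacing preserved", {
  v <- volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)),
              spacing_mm = c(0.7, 0.7, 1.2))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$spacing_mm, v$spacing_mm, tolerance = 1e-6)
  expect_equal(v2$data, v$data, tolerance = 1e-6)
})
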