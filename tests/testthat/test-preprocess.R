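test_that("isotropic resampling gets the shape arithmetic right", {
  v <- volume(array(rnorm(16^3), c(16, 16, 16)), spacing_mm = 1)
  r <- resample_isotropic(v, 0.5)
  expect_equal(dim(r), c(32L, 32L, 32L))
  expect_equal(r$spacing_mm, rep(0.5, 3))
  van <- volume(array(rnorm(16 * 16 * 8), c(16, 16, 8)),
                spacing_mm = c(0.5, 0.5, 2))
  ran <- resample_isotropic(van, 1)
  expect_equal(dim(ran), c(8L, 8L, 16L))
})

test_that("resampling a volume already on the target grid is the identity", {
  v <- volume(array(rnorm(12^3), c(12, 12, 12)), spacing_mm = 0.5)
  r <- resample_isotropic(v, 0.5)
  expect_equal(r$data, v$data, tolerance = 1e-12)
})

test_that("resampling preserves constants and physical extent", {
  v <- volume(array(7.5, c(10, 10, 10)), spacing_mm = 1.3)
  r <- resample_isotropic(v, 0.4)
  expect_true(all(abs(r$data - 7.5) < 1e-12))
  expect_lte(max(abs(dim(r) * r$spacing_mm - dim(v) * v$spacing_mm)),
             max(v$spacing_mm))
})

test_that("nearest-neighbour resampling keeps masks binary", {
  m <- array(0L, c(10, 10, 10)); m[4:6, 4:6, 4:6] <- 1L
  v <- volume(m, spacing_mm = 1)
  r <- resample_isotropic(v, 0.6, method = "nearest")
  expect_true(all(r$data %in% c(0, 1)))
  expect_gt(sum(r$data), 0)
})

test_that("intensity windowing clamps and rescales as specified", {
  v <- volume(array(c(-100, 2500, 1000, 0, 2000, 500,
                      rep(0, 2)), c(2, 2, 2)), 1)
  w <- window_intensity(v)
  expect_equal(w$data[1, 1, 1], 0)    # -100 HU -> 0
  expect_equal(w$data[2, 1, 1], 1)    # 2500 HU -> 1
  expect_equal(w$data[1, 2, 1], 0.5)  # 1000 HU -> midpoint
  expect_equal(w$data[1, 1, 2], 1)    # 2000 HU -> top of window
  z <- window_intensity(volume(array(0, c(2, 2, 2)), 1))
  expect_true(all(z$data == 0))
  expect_error(window_intensity(v, 10, 10), "lo")
})

test_that("windowing is idempotent on its output scale", {
  v <- volume(array(runif(4^3, -500, 3000), c(4, 4, 4)), 1)
  w <- window_intensity(v)
  w2 <- window_intensity(w, 0, 1)
  expect_equal(w2$data, w$data, tolerance = 1e-12)
})

test_that("patch extraction crops, pads, and keeps provenance aligned", {
  arr <- array(rnorm(32 * 32 * 8), c(32, 32, 8))
  msk <- array(rbinom(32 * 32 * 8, 1, 0.1), c(32, 32, 8))
  v <- volume(arr, 0.5); m <- volume(msk, 0.5)
  ps <- extract_patches(v, m, side = 32)
  expect_length(ps$patches, 8)
  expect_equal(ps$patches[[3]], arr[, , 3])        # identity when side matches
  # centre crop from a larger slice
  big <- volume(array(rnorm(40 * 40 * 2), c(40, 40, 2)), 0.5)
  bigm <- volume(array(0L, c(40, 40, 2)), 0.5)
  pc <- extract_patches(big, bigm, side = 32)
  expect_equal(pc$patches[[1]], big$data[5:36, 5:36, 1])
  # zero pad from a smaller slice
  small <- volume(array(1, c(20, 20, 2)), 0.5)
  sm <- extract_patches(small, volume(array(0L, c(20, 20, 2)), 0.5), side = 32)
  expect_equal(dim(sm$patches[[1]]), c(32L, 32L))
  expect_equal(sum(sm$patches[[1]]), 400)          # padding contributes zeros
  expect_error(extract_patches(v, volume(array(0L, c(16, 16, 8)), 0.5)),
               "grid")
})

test_that("empty-mask slices are dropped only when requested", {
  msk <- array(0L, c(16, 16, 4)); msk[8, 8, 2] <- 1L
  v <- volume(array(0, c(16, 16, 4)), 1); m <- volume(msk, 1)
  expect_length(extract_patches(v, m, side = 16)$patches, 4)
  kept <- extract_patches(v, m, side = 16, drop_empty = TRUE)
  expect_length(kept$patches, 1)
  expect_equal(kept$provenance$slice, 2)
})

test_that("augmentation applies one dihedral transform jointly to patch and mask", {
  p <- matrix(rnorm(64), 8, 8)
  m <- matrix(rbinom(64, 1, 0.3), 8, 8)
  a <- augment(p, m, seed = 1L)
  expect_identical(dim(a$patch), dim(p))
  expect_equal(sum(a$mask), sum(m))                 # rigid transform
  expect_equal(augment(p, m, seed = 1L)$patch, a$patch)  # seeded
  # identity element
  expect_equal(cowseg:::apply_dihedral(p, 0, FALSE), p)
  # two quarter turns compose to a half turn
  r2 <- cowseg:::apply_dihedral(cowseg:::apply_dihedral(p, 1, FALSE), 1, FALSE)
  expect_equal(r2, cowseg:::apply_dihedral(p, 2, FALSE))
  # Dice of a mask with its own transform is preserved under joint transforms
  expect_equal(dice_coefficient(array(a$mask, c(8, 8, 1)),
                                array(a$mask, c(8, 8, 1)))$dice, 1)
})
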