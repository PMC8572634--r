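# independent per-pixel re-implementation of the loss used as oracle
loss_oracle <- function(I, S, O, F, B, eps = 1e-6) {
  n <- length(I)
  rec <- 0
  for (i in seq_len(n))
    rec <- rec + (I[i] - (F[i] * O[i] + B[i] * (1 - O[i])))^2
  num <- 0; den <- eps
  for (i in seq_len(n)) {
    num <- num + 2 * O[i] * S[i]
    den <- den + O[i]^2 + S[i]^2
  }
  rec / n + (1 - (num + eps) / den)
}

test_that("loss decomposes as reconstruction + Dice and vanishes for perfect output", {
  set.seed(1)
  I <- matrix(runif(16), 4)
  S <- matrix(rbinom(16, 1, 0.5), 4)
  out <- list(O = matrix(runif(16), 4), F = matrix(rnorm(16), 4),
              B = matrix(rnorm(16), 4))
  lc <- multitask_loss(I, S, out)
  expect_equal(lc$total, lc$reconstruction + lc$dice, tolerance = 1e-12)
  perfect <- multitask_loss(I, S, list(O = S, F = I, B = I))
  expect_equal(perfect$total, 0, tolerance = 1e-9)
  # zero-overlap prediction drives the Dice term to 1
  disj <- multitask_loss(I, S, list(O = 1 - S, F = I, B = I))
  expect_equal(disj$dice, 1, tolerance = 1e-5)
  expect_error(multitask_loss(I, S, list(O = matrix(2, 4, 4), F = I, B = I)),
               "O must lie")
  expect_error(multitask_loss(I, matrix(0, 2, 2), out), "shape")
})

test_that("loss matches an independent per-pixel oracle on random 4x4 inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    I <- matrix(runif(16), 4); S <- matrix(rbinom(16, 1, 0.4), 4)
    O <- matrix(runif(16), 4); F <- matrix(rnorm(16), 4)
    B <- matrix(rnorm(16), 4)
    lc <- multitask_loss(I, S, list(O = O, F = F, B = B))
    expect_equal(lc$total, loss_oracle(I, S, O, F, B), tolerance = 1e-6)
  }
})

test_that("Dice loss reproduces hand-computed cases", {
  S <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice_loss(S, S), 0, tolerance = 1e-6)
  expect_equal(dice_loss(1 - S, S), 1, tolerance = 1e-6)
  # O = 0.5 everywhere, half-filled S: 1 - (2*1)/(1+2) = 1/3
  expect_equal(dice_loss(matrix(0.5, 2, 2), S), 1 / 3, tolerance = 1e-6)
  z <- matrix(0, 2, 2)
  expect_equal(dice_loss(z, z), 0)    # both empty = perfect agreement
})

test_that("reconstruction term ignores F where O = 0 and B where O = 1", {
  set.seed(2)
  I <- matrix(runif(16), 4)
  O <- matrix(rbinom(16, 1, 0.5), 4)
  S <- O
  F1 <- matrix(rnorm(16), 4); F2 <- F1; F2[O == 0] <- 99
  B1 <- matrix(rnorm(16), 4); B2 <- B1; B2[O == 1] <- -99
  l1 <- multitask_loss(I, S, list(O = O, F = F1, B = B1))
  l2 <- multitask_loss(I, S, list(O = O, F = F2, B = B2))
  expect_equal(l1$reconstruction, l2$reconstruction, tolerance = 1e-12)
})

test_that("analytic gradients of the loss agree with finite differences", {
  set.seed(3)
  I <- matrix(runif(16), 4); S <- matrix(rbinom(16, 1, 0.4), 4)
  out <- list(O = matrix(runif(16), 4), F = matrix(rnorm(16), 4),
              B = matrix(rnorm(16), 4))
  gr <- cowseg:::multitask_loss_grad(I, S, out)
  h <- 1e-6
  for (fld in c("O", "F", "B")) {
    for (idx in c(1, 6, 11, 16)) {
      o1 <- out; o2 <- out
      o1[[fld]][idx] <- o1[[fld]][idx] + h
      o2[[fld]][idx] <- o2[[fld]][idx] - h
      fd <- (multitask_loss(I, S, o1)$total -
               multitask_loss(I, S, o2)$total) / (2 * h)
      expect_equal(gr[[paste0("d", fld)]][idx], fd, tolerance = 1e-4)
    }
  }
})

test_that("backprop through the full network matches finite differences", {
  set.seed(4)
  net <- build_model(model_config(levels = 2, base_filters = 2,
                                  aspp_dilations = c(1, 2)), seed = 5L)
  x <- matrix(runif(64), 8, 8)
  S <- matrix(rbinom(64, 1, 0.3), 8, 8)
  fwd <- cowseg:::model_forward(net, x)
  gr <- cowseg:::multitask_loss_grad(x, S, fwd$out)
  g <- cowseg:::model_backward(net, fwd, gr$dO, gr$dF, gr$dB)
  lossfn <- function(n) {
    f <- cowseg:::model_forward(n, x)
    multitask_loss(x, S, f$out)$total
  }
  h <- 1e-5
  for (nm in c("enc1", "enc2_n", "aspp_d2", "aspp_gap", "aspp_fuse",
               "dec1", "head_O", "head_F", "head_B")) {
    for (f in c("W", "b")) {
      len <- length(net$params[[nm]][[f]])
      for (idx in unique(c(1L, len))) {
        n1 <- net; n2 <- net
        n1$params[[nm]][[f]][idx] <- n1$params[[nm]][[f]][idx] + h
        n2$params[[nm]][[f]][idx] <- n2$params[[nm]][[f]][idx] - h
        fd <- (lossfn(n1) - lossfn(n2)) / (2 * h)
        expect_equal(g[[nm]][[f]][idx], fd, tolerance = 1e-3)
      }
    }
  }
})

test_that("multitask nets emit three aligned maps and single-task nets one", {
  mt <- build_model(model_config(levels = 4, base_filters = 2), seed = 1L)
  fwd <- cowseg:::model_forward(mt, matrix(0, 288, 288))
  expect_named(fwd$out, c("O", "F", "B"))
  expect_true(all(vapply(fwd$out, function(m)
    identical(dim(m), c(288L, 288L)), logical(1))))
  expect_true(all(is.finite(unlist(fwd$out))))     # finite on all-zeros input
  expect_true(min(fwd$out$O) >= 0 && max(fwd$out$O) <= 1)
  stk <- build_model(model_config(levels = 4, base_filters = 2,
                                  heads = "singletask"), seed = 1L)
  expect_named(cowseg:::model_forward(stk, matrix(0, 64, 64))$out, "O")
})

test_that("parameter count is reproducible from the config alone", {
  n1 <- cowseg:::n_parameters(build_model(model_config(base_filters = 4),
                                          seed = 1L))
  n2 <- cowseg:::n_parameters(build_model(model_config(base_filters = 4),
                                          seed = 99L))
  expect_identical(n1, n2)
})

test_that("incompatible input sides fail with a shape error", {
  net <- build_model(model_config(levels = 4, base_filters = 2), seed = 1L)
  expect_error(cowseg:::model_forward(net, matrix(0, 60, 60)), "divisible")
})

test_that("training is deterministic, reduces the loss, and overfits a toy set", {
  set.seed(6)
  patches <- lapply(1:12, function(i) {
    m <- matrix(0, 16, 16); m[5:12, 5:12] <- 1
    p <- 0.1 + 0.6 * m + matrix(rnorm(256, 0, 0.02), 16)
    list(p = p, m = m)
  })
  ps <- structure(list(patches = lapply(patches, `[[`, "p"),
                       masks = lapply(patches, `[[`, "m"),
                       provenance = data.frame(volume_id = "toy",
                                               slice = 1:12),
                       side = 16L), class = "cow_patchset")
  net <- build_model(model_config(levels = 2, base_filters = 4,
                                  aspp_dilations = c(1, 2)), seed = 2L)
  tc <- train_config(learning_rate = 3e-3, epochs = 8, batch_size = 4,
                     seed = 3L, augment = FALSE)
  fit1 <- train(net, ps, tc)
  fit2 <- train(net, ps, tc)
  expect_equal(fit1$history, fit2$history, tolerance = 1e-12)
  expect_lte(tail(fit1$history$total, 1), fit1$history$total[1])
  expect_lt(tail(fit1$history$dice, 1), 0.5)   # the toy task is learnable
  expect_error(train(net, structure(list(patches = list()),
                                    class = "cow_patchset"), tc),
               "non-empty")
})

test_that("volume prediction reassembles slices on the input grid", {
  net <- build_model(model_config(levels = 2, base_filters = 2,
                                  aspp_dilations = c(1, 2)), seed = 1L)
  v <- volume(array(runif(20 * 20 * 5), c(20, 20, 5)), 1)
  pr <- predict_volume(net, v)
  expect_equal(dim(pr$mask), dim(v))
  expect_equal(pr$mask$spacing_mm, v$spacing_mm)
  empty <- predict_volume(net, v, threshold = 1)
  expect_equal(sum(empty$mask$data), 0)        # probabilities stay below 1
  expect_error(predict_volume(list(), v), "cow_model")
})
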