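#' Configuration of the multitask segmentation network
#'
#' Describes the encoder-decoder: `levels` encoder stages of 3x3 convolution
#' + instance normalization + ReLU with 2x2 max-pooling between stages
#' (per-image spatial normalization statistics, so inference on single
#' slices matches training exactly), an atrous spatial pyramid
#' pooling (ASPP) bottleneck that concatenates parallel dilated convolutions
#' (rates `aspp_dilations`) with a global-average-pooling branch, a decoder
#' of factor-2 bilinear upsampling with skip concatenations, and either
#' three output heads (`"multitask"`: segmentation probability map `O` via
#' sigmoid, plus linear foreground `F` and background `B` reconstructions in
#' windowed \[0, 1\] intensity units) or a single segmentation head
#' (`"singletask"`, the U-Net-style baseline).
#'
#' @param levels encoder depth (default 4); input sides must be divisible by
#'   `2^(levels - 1)`.
#' @param kernel_size convolution kernel size (default 3).
#' @param base_filters channels at the first level, doubled per level
#'   (default 16; small so CPU training stays practical).
#' @param aspp_dilations increasing positive dilation rates (default
#'   `c(1, 2, 4, 8)`).
#' @param include_global_pool include the ASPP global-average-pooling branch.
#' @param heads `"multitask"` or `"singletask"`.
#' @return An object of class `cow_model_config`.
#' @export
model_config <- function(levels = 4L, kernel_size = 3L, base_filters = 16L,
                         aspp_dilations = c(1L, 2L, 4L, 8L),
                         include_global_pool = TRUE,
                         heads = c("multitask", "singletask")) {
  heads <- match.arg(heads)
  if (levels < 1) stop("`levels` must be >= 1")
  if (any(aspp_dilations <= 0) || is.unsorted(aspp_dilations, strictly = TRUE))
    stop("`aspp_dilations` must be positive and strictly increasing")
  structure(list(levels = as.integer(levels),
                 kernel_size = as.integer(kernel_size),
                 base_filters = as.integer(base_filters),
                 aspp_dilations = as.integer(aspp_dilations),
                 include_global_pool = isTRUE(include_global_pool),
                 heads = heads),
            class = "cow_model_config")
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with initial learning
#' rate 1e-4, 50 epochs, batch size 32. Scaled-down experiments override
#' them explicitly. `recon_weight` is the weight of the reconstruction term
#' relative to the Dice term (the loss is defined with unit weights; the
#' knob exists because the balance is otherwise an untestable assumption).
#'
#' @param learning_rate Adam step size.
#' @param epochs number of passes over the training patches.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling shuffling, augmentation and
#'   initialisation order effects during training.
#' @param augment apply random rotation/flip augmentation per patch per epoch.
#' @param recon_weight weight of the reconstruction loss term (default 1).
#' @return An object of class `cow_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 50L, batch_size = 32L,
                         seed = 1L, augment = TRUE, recon_weight = 1) {
  stopifnot(learning_rate > 0, epochs > 0, batch_size > 0, recon_weight >= 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 augment = isTRUE(augment), recon_weight = recon_weight),
            class = "cow_train_config")
}

#' Build the (multitask or single-task) segmentation network
#'
#' Instantiates He-initialised parameters for the architecture described by
#' the config. The parameter count is a pure function of the config, and
#' initialisation is deterministic given `seed`.
#'
#' @param cfg a [model_config()].
#' @param in_channels input channels (1 for CTA slices).
#' @param seed RNG seed for initialisation.
#' @return An object of class `cow_model`.
#' @export
build_model <- function(cfg, in_channels = 1L, seed = 1L) {
  stopifnot(inherits(cfg, "cow_model_config"))
  L <- cfg$levels
  k <- cfg$kernel_size
  f <- cfg$base_filters * 2^(seq_len(L) - 1L)
  params <- with_seed(seed, {
    p <- list()
    cin <- in_channels
    for (l in seq_len(L)) {
      p[[paste0("enc", l)]] <- init_conv(cin, f[l], k)
      p[[paste0("enc", l, "_n")]] <- init_norm(f[l])
      cin <- f[l]
    }
    fb <- f[L]
    for (i in seq_along(cfg$aspp_dilations)) {
      p[[paste0("aspp_d", i)]] <- init_conv(fb, fb, k)
      p[[paste0("aspp_d", i, "_n")]] <- init_norm(fb)
    }
    if (cfg$include_global_pool)
      p[["aspp_gap"]] <- init_conv(fb, fb, 1L)
    nbr <- length(cfg$aspp_dilations) + cfg$include_global_pool
    p[["aspp_fuse"]] <- init_conv(nbr * fb, fb, 1L)
    p[["aspp_fuse_n"]] <- init_norm(fb)
    if (L > 1) {
      for (l in rev(seq_len(L - 1L))) {
        p[[paste0("dec", l)]] <- init_conv(f[l + 1] + f[l], f[l], k)
        p[[paste0("dec", l, "_n")]] <- init_norm(f[l])
      }
    }
    p[["head_O"]] <- init_conv(f[1], 1L, 1L)
    if (cfg$heads == "multitask") {
      p[["head_F"]] <- init_conv(f[1], 1L, 1L)
      p[["head_B"]] <- init_conv(f[1], 1L, 1L)
    }
    p
  })
  structure(list(cfg = cfg, params = params, in_channels = as.integer(in_channels),
                 seed = as.integer(seed)),
            class = "cow_model")
}

#' @export
print.cow_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf("<cow_model> %s, %d levels, base %d filters, %s parameters\n",
              x$cfg$heads, x$cfg$levels, x$cfg$base_filters,
              format(np, big.mark = ",")))
  invisible(x)
}

n_parameters <- function(net)
  sum(vapply(net$params, function(p) length(p$W) + length(p$b), numeric(1)))

check_input_side <- function(net, d) {
  div <- 2^(net$cfg$levels - 1L)
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop(sprintf("input side %dx%d not divisible by 2^(levels-1) = %d",
                 d[1], d[2], div))
}

# Forward pass on one [H, W, C_in] input. Returns O/F/B maps plus the cache
# needed by model_backward().
model_forward <- function(net, x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  check_input_side(net, dim(x))
  p <- net$params
  cfg <- net$cfg
  L <- cfg$levels
  k <- cfg$kernel_size
  cache <- list(enc = vector("list", L), input_dims = dim(x))

  h <- x
  for (l in seq_len(L)) {
    cv <- conv_fwd(h, p[[paste0("enc", l)]], k)
    nm <- norm_fwd(cv$out, p[[paste0("enc", l, "_n")]])
    rl <- relu_fwd(nm$out)
    st <- list(conv = cv$cache, norm = nm$cache, relu = rl$cache, act = rl$out)
    if (l < L) {
      pl <- pool_fwd(rl$out)
      st$pool <- pl$cache
      h <- pl$out
    } else h <- rl$out
    cache$enc[[l]] <- st
  }

  # ASPP bottleneck
  branches <- list()
  bcache <- list()
  for (i in seq_along(cfg$aspp_dilations)) {
    cv <- conv_fwd(h, p[[paste0("aspp_d", i)]], k, cfg$aspp_dilations[i])
    nm <- norm_fwd(cv$out, p[[paste0("aspp_d", i, "_n")]])
    rl <- relu_fwd(nm$out)
    branches[[i]] <- rl$out
    bcache[[i]] <- list(conv = cv$cache, norm = nm$cache, relu = rl$cache)
  }
  db <- dim(h)
  if (cfg$include_global_pool) {
    gmean <- colMeans(matrix(h, db[1] * db[2], db[3]))
    gz <- as.numeric(p$aspp_gap$W %*% gmean + p$aspp_gap$b)
    grl <- pmax(gz, 0)
    gb <- array(rep(grl, each = db[1] * db[2]), db)
    branches[[length(branches) + 1L]] <- gb
    cache$gap <- list(gmean = gmean, gz = gz, dims = db)
  }
  a <- branches[[1]]
  for (i in seq_along(branches)[-1]) a <- cat_channels(a, branches[[i]])
  fz <- conv_fwd(a, p$aspp_fuse, 1L)
  fnm <- norm_fwd(fz$out, p$aspp_fuse_n)
  frl <- relu_fwd(fnm$out)
  cache$aspp <- list(branches = bcache, fuse = fz$cache, fuse_norm = fnm$cache,
                     fuse_relu = frl$cache,
                     nbranch = length(branches), bottleneck_dims = db)
  h <- frl$out

  # decoder
  if (L > 1) {
    cache$dec <- vector("list", L - 1L)
    for (l in rev(seq_len(L - 1L))) {
      pre_dims <- dim(h)
      u <- up_fwd(h)
      skip <- cache$enc[[l]]$act
      s <- cat_channels(u, skip)
      cv <- conv_fwd(s, p[[paste0("dec", l)]], k)
      nm <- norm_fwd(cv$out, p[[paste0("dec", l, "_n")]])
      rl <- relu_fwd(nm$out)
      cache$dec[[l]] <- list(pre_dims = pre_dims, u_channels = dim(u)[3],
                             conv = cv$cache, norm = nm$cache, relu = rl$cache)
      h <- rl$out
    }
  }

  oz <- conv_fwd(h, p$head_O, 1L)
  O <- sigmoid(oz$out[, , 1])
  cache$head_O <- oz$cache
  out <- list(O = O)
  if (cfg$heads == "multitask") {
    fzh <- conv_fwd(h, p$head_F, 1L)
    bzh <- conv_fwd(h, p$head_B, 1L)
    out$F <- fzh$out[, , 1]
    out$B <- bzh$out[, , 1]
    cache$head_F <- fzh$cache
    cache$head_B <- bzh$cache
  }
  cache$decoded <- h
  list(out = out, cache = cache)
}

# Backward pass: dO/dF/dB are gradients of the scalar loss w.r.t. the output
# maps (dO w.r.t. the post-sigmoid probabilities). Returns per-parameter
# gradients.
model_backward <- function(net, fwd, dO, dF = NULL, dB = NULL) {
  p <- net$params
  cfg <- net$cfg
  L <- cfg$levels
  cache <- fwd$cache
  grads <- grads_zero(p)

  # heads
  O <- fwd$out$O
  doz <- dO * O * (1 - O)                       # through sigmoid
  hb <- conv_bwd(array(doz, c(dim(doz), 1L)), p$head_O, cache$head_O)
  grads$head_O$W <- hb$dW; grads$head_O$b <- hb$db
  dh <- hb$dx
  if (cfg$heads == "multitask") {
    fb <- conv_bwd(array(dF, c(dim(dF), 1L)), p$head_F, cache$head_F)
    bb <- conv_bwd(array(dB, c(dim(dB), 1L)), p$head_B, cache$head_B)
    grads$head_F$W <- fb$dW; grads$head_F$b <- fb$db
    grads$head_B$W <- bb$dW; grads$head_B$b <- bb$db
    dh <- dh + fb$dx + bb$dx
  }

  # decoder (reverse order of forward: l = 1 .. L-1)
  dskip <- vector("list", L)                    # gradients into encoder skips
  if (L > 1) {
    for (l in seq_len(L - 1L)) {
      st <- cache$dec[[l]]
      dr <- relu_bwd(dh, st$relu)
      nb <- norm_bwd(dr, p[[paste0("dec", l, "_n")]], st$norm)
      grads[[paste0("dec", l, "_n")]]$W <- nb$dW
      grads[[paste0("dec", l, "_n")]]$b <- nb$db
      cb <- conv_bwd(nb$dx, p[[paste0("dec", l)]], st$conv)
      grads[[paste0("dec", l)]]$W <- cb$dW
      grads[[paste0("dec", l)]]$b <- cb$db
      uc <- st$u_channels
      du <- cb$dx[, , seq_len(uc), drop = FALSE]
      dskip[[l]] <- cb$dx[, , -seq_len(uc), drop = FALSE]
      dh <- up_bwd(du, st$pre_dims)
    }
  }

  # ASPP
  asp <- cache$aspp
  dfr <- relu_bwd(dh, asp$fuse_relu)
  fnb <- norm_bwd(dfr, p$aspp_fuse_n, asp$fuse_norm)
  grads$aspp_fuse_n$W <- fnb$dW; grads$aspp_fuse_n$b <- fnb$db
  fb <- conv_bwd(fnb$dx, p$aspp_fuse, asp$fuse)
  grads$aspp_fuse$W <- fb$dW; grads$aspp_fuse$b <- fb$db
  db <- asp$bottleneck_dims
  fbneck <- db[3]
  dbneck <- array(0, db)
  for (i in seq_along(cfg$aspp_dilations)) {
    dbr <- fb$dx[, , ((i - 1) * fbneck + 1):(i * fbneck), drop = FALSE]
    dbr <- relu_bwd(dbr, asp$branches[[i]]$relu)
    nb <- norm_bwd(dbr, p[[paste0("aspp_d", i, "_n")]], asp$branches[[i]]$norm)
    grads[[paste0("aspp_d", i, "_n")]]$W <- nb$dW
    grads[[paste0("aspp_d", i, "_n")]]$b <- nb$db
    cb <- conv_bwd(nb$dx, p[[paste0("aspp_d", i)]], asp$branches[[i]]$conv)
    grads[[paste0("aspp_d", i)]]$W <- cb$dW
    grads[[paste0("aspp_d", i)]]$b <- cb$db
    dbneck <- dbneck + cb$dx
  }
  if (cfg$include_global_pool) {
    i <- length(cfg$aspp_dilations)
    dgb <- fb$dx[, , (i * fbneck + 1):((i + 1) * fbneck), drop = FALSE]
    dgrl <- colSums(matrix(dgb, db[1] * db[2], fbneck))
    dgz <- dgrl * (cache$gap$gz > 0)
    grads$aspp_gap$W <- outer(dgz, cache$gap$gmean)
    grads$aspp_gap$b <- dgz
    dgmean <- as.numeric(crossprod(p$aspp_gap$W, dgz))
    dbneck <- dbneck + array(rep(dgmean / (db[1] * db[2]),
                                 each = db[1] * db[2]), db)
  }
  dh <- dbneck

  # encoder
  for (l in rev(seq_len(L))) {
    st <- cache$enc[[l]]
    if (l < L) dh <- pool_bwd(dh, st$pool)
    if (!is.null(dskip[[l]])) dh <- dh + dskip[[l]]
    dr <- relu_bwd(dh, st$relu)
    nb <- norm_bwd(dr, p[[paste0("enc", l, "_n")]], st$norm)
    grads[[paste0("enc", l, "_n")]]$W <- nb$dW
    grads[[paste0("enc", l, "_n")]]$b <- nb$db
    cb <- conv_bwd(nb$dx, p[[paste0("enc", l)]], st$conv)
    grads[[paste0("enc", l)]]$W <- cb$dW
    grads[[paste0("enc", l)]]$b <- cb$db
    dh <- cb$dx
  }

  grads
}

#' Soft Dice loss between a probability map and a binary mask
#'
#' `1 - 2 * sum(O * S) / (sum(O^2) + sum(S^2) + eps)` with sums over all
#' pixels of one image. Equals 0 for a perfect binary prediction and 1 for
#' disjoint nonempty maps. When both `O` and `S` are entirely zero the term
#' is 0 (perfect agreement), enforced by the smoothing constant.
#'
#' @param O probability map in \[0, 1\].
#' @param S binary mask of the same shape.
#' @param eps smoothing constant (default 1e-6).
#' @return scalar in \[0, 1\].
#' @export
dice_loss <- function(O, S, eps = 1e-6) {
  if (!identical(dim(O), dim(S))) stop("shape mismatch between O and S")
  num <- 2 * sum(O * S) + eps
  den <- sum(O^2) + sum(S^2) + eps
  1 - num / den
}

# gradient of dice_loss w.r.t. O
dice_loss_grad <- function(O, S, eps = 1e-6) {
  num <- 2 * sum(O * S) + eps
  den <- sum(O^2) + sum(S^2) + eps
  -(2 * S * den - num * 2 * O) / den^2
}

#' The multitask reconstruction + Dice loss
#'
#' For an input image `I`, ground-truth mask `S` and network outputs
#' `(O, F, B)`, the loss is the per-pixel mean squared error between `I` and
#' the probability-weighted blend `F * O + B * (1 - O)`, plus the soft Dice
#' loss between `O` and `S`:
#' `J = mean((I - (F*O + B*(1-O)))^2) + 1 - 2*sum(O*S) / (sum(O^2) + sum(S^2))`.
#' A perfect prediction (`O = S` binary, `F = I` on the vessel, `B = I`
#' elsewhere) gives `J = 0`. Inputs may be single images or lists over a
#' batch (spatial sums per image, mean over the batch).
#'
#' @param I input image (windowed intensities), or list of images.
#' @param S binary mask in `{0, 1}`, or list.
#' @param out list with `O`, `F`, `B` (as from `model_forward()`), or a list
#'   of such lists for a batch.
#' @param eps Dice smoothing constant.
#' @param recon_weight weight on the reconstruction term in `total`
#'   (default 1, giving `total = reconstruction + dice`).
#' @return list with `reconstruction`, `dice` and `total`.
#' @export
multitask_loss <- function(I, S, out, eps = 1e-6, recon_weight = 1) {
  if (is.list(I)) {
    comps <- mapply(function(i, s, o) multitask_loss(i, s, o, eps, recon_weight),
                    I, S, out, SIMPLIFY = FALSE)
    rec <- mean(vapply(comps, `[[`, numeric(1), "reconstruction"))
    dic <- mean(vapply(comps, `[[`, numeric(1), "dice"))
    return(list(reconstruction = rec, dice = dic,
                total = recon_weight * rec + dic))
  }
  if (!identical(dim(I), dim(S)) || !identical(dim(I), dim(out$O)))
    stop("shape mismatch among I, S and model outputs")
  if (min(out$O) < -1e-9 || max(out$O) > 1 + 1e-9)
    stop("O must lie in [0, 1]")
  R <- out$F * out$O + out$B * (1 - out$O)
  rec <- mean((I - R)^2)
  dic <- dice_loss(out$O, S, eps)
  list(reconstruction = rec, dice = dic, total = recon_weight * rec + dic)
}

# loss gradients w.r.t. O, F, B for one image
multitask_loss_grad <- function(I, S, out, eps = 1e-6, recon_weight = 1) {
  n <- length(I)
  R <- out$F * out$O + out$B * (1 - out$O)
  dR <- recon_weight * 2 * (R - I) / n
  list(dO = dR * (out$F - out$B) + dice_loss_grad(out$O, S, eps),
       dF = dR * out$O,
       dB = dR * (1 - out$O))
}

#' Train a segmentation network on a patch set
#'
#' Plain minibatch Adam. Multitask models optimise reconstruction + Dice;
#' single-task models optimise the Dice term only. Shuffling and
#' augmentation draws are controlled by `tc$seed`, so two runs with the same
#' configuration, data and seed produce identical histories and weights.
#'
#' @param net a [build_model()] network.
#' @param patches a [extract_patches()] patch set (patches windowed to
#'   \[0, 1\]).
#' @param tc a [train_config()].
#' @param quiet suppress per-epoch messages.
#' @return list with `net` (trained) and `history` (data.frame of mean
#'   per-epoch `reconstruction`, `dice`, `total`).
#' @export
train <- function(net, patches, tc = train_config(), quiet = TRUE) {
  stopifnot(inherits(net, "cow_model"), inherits(tc, "cow_train_config"))
  if (!inherits(patches, "cow_patchset") || length(patches$patches) == 0)
    stop("training requires a non-empty patch set")
  multitask <- net$cfg$heads == "multitask"
  n <- length(patches$patches)
  params <- net$params
  state <- adam_init(params)
  hist <- data.frame(epoch = integer(0), reconstruction = numeric(0),
                     dice = numeric(0), total = numeric(0))
  epoch_seeds <- derive_seeds(tc$seed, tc$epochs)
  for (ep in seq_len(tc$epochs)) {
    ord <- with_seed(epoch_seeds[ep], sample.int(n))
    aug_seeds <- derive_seeds(epoch_seeds[ep] %% 1000000L + ep, n)
    ep_rec <- 0; ep_dic <- 0; nb <- 0
    bstarts <- seq(1, n, by = tc$batch_size)
    net$params <- params
    for (bs in bstarts) {
      idx <- ord[bs:min(bs + tc$batch_size - 1L, n)]
      gacc <- grads_zero(params)
      brec <- 0; bdic <- 0
      for (ii in seq_along(idx)) {
        i <- idx[ii]
        pa <- patches$patches[[i]]
        ma <- patches$masks[[i]]
        if (tc$augment) {
          au <- augment(pa, ma, aug_seeds[i])
          pa <- au$patch; ma <- au$mask
        }
        fwd <- model_forward(net, pa)
        out <- fwd$out
        if (multitask) {
          lc <- multitask_loss(pa, ma, out, recon_weight = tc$recon_weight)
          gr <- multitask_loss_grad(pa, ma, out, recon_weight = tc$recon_weight)
          g <- model_backward(net, fwd, gr$dO, gr$dF, gr$dB)
        } else {
          lc <- list(reconstruction = 0, dice = dice_loss(out$O, ma),
                     total = dice_loss(out$O, ma))
          g <- model_backward(net, fwd, dice_loss_grad(out$O, ma))
        }
        gacc <- grads_add(gacc, g)
        brec <- brec + lc$reconstruction
        bdic <- bdic + lc$dice
      }
      gacc <- grads_scale(gacc, 1 / length(idx))
      upd <- adam_step(params, gacc, state, tc$learning_rate)
      params <- upd$params
      state <- upd$state
      net$params <- params
      ep_rec <- ep_rec + brec / length(idx)
      ep_dic <- ep_dic + bdic / length(idx)
      nb <- nb + 1
    }
    hist <- rbind(hist, data.frame(epoch = ep, reconstruction = ep_rec / nb,
                                   dice = ep_dic / nb,
                                   total = tc$recon_weight * ep_rec / nb +
                                     ep_dic / nb))
    if (!quiet)
      message(sprintf("epoch %d: recon %.5f dice %.5f", ep, ep_rec / nb,
                      ep_dic / nb))
  }
  net$params <- params
  list(net = net, history = hist)
}

#' Save and load model checkpoints
#'
#' Checkpoints are written as RDS with a JSON sidecar (`<path>.json`)
#' recording the architecture config, initialisation seed and parameter
#' count, so a checkpoint is identifiable without loading it.
#'
#' @param net a [build_model()] network.
#' @param path checkpoint file path (conventionally `.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the network.
#' @export
save_model <- function(net, path) {
  stopifnot(inherits(net, "cow_model"))
  saveRDS(net, path)
  sidecar <- list(config = unclass(net$cfg), seed = net$seed,
                  n_parameters = n_parameters(net))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "cow_model")) stop("not a cowseg model checkpoint")
  net
}

#' Segment a preprocessed volume slice by slice
#'
#' Runs the network on every axial slice (centre-padded/cropped to a side
#' divisible by `2^(levels-1)`), reassembles the probability maps on the
#' input grid along z, and binarises at `threshold`.
#'
#' @param net a trained [build_model()] network.
#' @param v a [volume()], already resampled and windowed to \[0, 1\].
#' @param threshold binarisation probability (default 0.5).
#' @return list with `mask` (binary [volume()]) and `prob` (probability
#'   [volume()]).
#' @export
predict_volume <- function(net, v, threshold = 0.5) {
  if (!inherits(net, "cow_model")) stop("`net` must be a cow_model")
  stopifnot(is_volume(v))
  d <- dim(v$data)
  div <- 2^(net$cfg$levels - 1L)
  side <- as.integer(div * ceiling(max(d[1], d[2]) / div))
  prob <- array(0, d)
  off1 <- (side - d[1]) %/% 2
  off2 <- (side - d[2]) %/% 2
  for (k in seq_len(d[3])) {
    sl <- crop_or_pad(v$data[, , k], side)
    O <- model_forward(net, sl)$out$O
    prob[, , k] <- O[off1 + seq_len(d[1]), off2 + seq_len(d[2])]
  }
  list(mask = volume(array(as.integer(prob >= threshold), d), v$spacing_mm,
                     v$origin_mm),
       prob = volume(prob, v$spacing_mm, v$origin_mm))
}
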