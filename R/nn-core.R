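# Neural-network primitives.
#
# Feature maps are [H, W, C] numeric arrays. A convolution is lowered to a
# single BLAS matmul via im2col (C++): weights are stored as a
# [C_out, k*k*C_in] matrix whose column order matches the im2col row order
# (channel-major, then kernel column, then kernel row). All layers cache
# what their backward pass needs; backprop is explicit, no autodiff.

conv_fwd <- function(x, par, k, dil = 1L) {
  d <- dim(x)
  cols <- im2col_cpp(as.numeric(x), d[1], d[2], d[3], k, dil)
  out <- par$W %*% cols + par$b
  list(out = array(t(out), c(d[1], d[2], nrow(par$W))),
       cache = list(cols = cols, dims = d, k = k, dil = dil))
}

conv_bwd <- function(dout, par, cache) {
  d <- cache$dims
  hw <- d[1] * d[2]
  G <- t(matrix(dout, hw, length(dout) / hw))      # C_out x HW
  dW <- G %*% t(cache$cols)
  db <- rowSums(G)
  dcols <- crossprod(par$W, G)                     # k2C x HW
  dx <- col2im_cpp(dcols, d[1], d[2], d[3], cache$k, cache$dil)
  list(dx = array(dx, d), dW = dW, db = db)
}

# Instance normalization: each channel standardised by its own spatial mean
# and variance (per image), then scaled/shifted by learned gamma/beta stored
# as par$W / par$b. Keeps single-image inference identical to training.
norm_fwd <- function(x, par, eps = 1e-5) {
  d <- dim(x)
  X <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu)
  v <- colMeans(xc^2)
  ivstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, ivstd, "*")
  Y <- sweep(sweep(xhat, 2, par$W, "*"), 2, par$b, "+")
  list(out = array(Y, d),
       cache = list(xhat = xhat, ivstd = ivstd, dims = d))
}

norm_bwd <- function(dout, par, cache) {
  d <- cache$dims
  n <- d[1] * d[2]
  dY <- matrix(dout, n, d[3])
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2, par$W, "*")
  # dX = ivstd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- sweep(dxhat, 2, s1 / n) - sweep(cache$xhat, 2, s2 / n, "*")
  dX <- sweep(dX, 2, cache$ivstd, "*")
  list(dx = array(dX, d), dW = dg, db = db)
}

init_norm <- function(c_out) list(W = rep(1, c_out), b = numeric(c_out))

relu_fwd <- function(x) {
  out <- x * (x > 0)
  list(out = out, cache = x > 0)
}

relu_bwd <- function(dout, cache) dout * cache

pool_fwd <- function(x) {
  d <- dim(x)
  r <- maxpool2_cpp(as.numeric(x), d[1], d[2], d[3])
  list(out = array(r$out, c(d[1] / 2, d[2] / 2, d[3])),
       cache = list(arg = r$arg, n = length(x), dims = d))
}

pool_bwd <- function(dout, cache) {
  array(maxpool2_back_cpp(as.numeric(dout), cache$arg, cache$n), cache$dims)
}

up_fwd <- function(x) {
  d <- dim(x)
  array(upsample2_cpp(as.numeric(x), d[1], d[2], d[3]),
        c(2 * d[1], 2 * d[2], d[3]))
}

up_bwd <- function(dout, in_dims) {
  array(upsample2_back_cpp(as.numeric(dout), in_dims[1], in_dims[2],
                           in_dims[3]), in_dims)
}

cat_channels <- function(a, b) {
  d <- dim(a)
  array(c(a, b), c(d[1], d[2], d[3] + dim(b)[3]))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# He-initialised conv parameter block
init_conv <- function(c_in, c_out, k) {
  list(W = matrix(rnorm(c_out * k * k * c_in, 0, sqrt(2 / (k * k * c_in))),
                  c_out, k * k * c_in),
       b = numeric(c_out))
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (f in c("W", "b")) {
      g <- grads[[nm]][[f]]
      state$m[[nm]][[f]] <- beta1 * state$m[[nm]][[f]] + (1 - beta1) * g
      state$v[[nm]][[f]] <- beta2 * state$v[[nm]][[f]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[f]] / bc1
      vhat <- state$v[[nm]][[f]] / bc2
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

grads_zero <- function(params)
  lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))

grads_add <- function(a, b) {
  for (nm in names(a)) {
    a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}

grads_scale <- function(a, s) {
  lapply(a, function(p) list(W = p$W * s, b = p$b * s))
}
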