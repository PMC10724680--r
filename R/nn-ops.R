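# Low-level volumetric network operations: strided 3D convolutions,
# transposed convolutions, activations, mean-absolute-deviation instance
# normalization, and Adam. Forward functions return a cache consumed by the
# matching backward function; backprop is exact (validated by numeric
# gradient checks in the test suite).

conv3d_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

#' @useDynLib mriharm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

conv3d_forward <- function(x, W, b, stride, pad) {
  dims <- dim(x)
  k <- dim(W)[1L]
  cout <- dim(W)[5L]
  col <- cpp_im2col3(x, as.integer(dims), as.integer(k),
                     as.integer(stride), as.integer(pad))
  Wm <- matrix(W, nrow = k^3 * dims[4L], ncol = cout)
  ym <- crossprod(col, Wm)
  ym <- ym + rep(b, each = nrow(ym))
  od <- c(conv3d_out_dim(dims[1L], k, stride, pad),
          conv3d_out_dim(dims[2L], k, stride, pad),
          conv3d_out_dim(dims[3L], k, stride, pad), cout)
  list(y = array(ym, dim = od), col = col, indim = dims,
       k = k, stride = stride, pad = pad)
}

conv3d_backward <- function(cache, W, dy) {
  k <- cache$k
  cout <- dim(W)[5L]
  dym <- matrix(dy, ncol = cout)
  dW <- array(cache$col %*% dym, dim = dim(W))
  db <- colSums(dym)
  Wm <- matrix(W, nrow = k^3 * cache$indim[4L], ncol = cout)
  dcol <- Wm %*% t(dym)
  dx <- cpp_col2im3(dcol, as.integer(cache$indim), as.integer(k),
                    as.integer(cache$stride), as.integer(cache$pad))
  list(dW = dW, db = db, dx = dx)
}

convt3d_out_dim <- function(n, k, stride, pad) stride * (n - 1L) + k - 2L * pad

# Transposed convolution: weights have dims (k, k, k, Cout, Cin); the
# forward pass is the adjoint of a strided convolution over the output grid.
convt3d_forward <- function(x, W, b, stride, pad) {
  dims <- dim(x)
  k <- dim(W)[1L]
  cout <- dim(W)[4L]
  cin <- dim(W)[5L]
  od <- c(convt3d_out_dim(dims[1L], k, stride, pad),
          convt3d_out_dim(dims[2L], k, stride, pad),
          convt3d_out_dim(dims[3L], k, stride, pad), cout)
  Wm <- matrix(W, nrow = k^3 * cout, ncol = cin)
  xm <- matrix(x, ncol = cin)
  colm <- Wm %*% t(xm)
  y <- cpp_col2im3(colm, as.integer(od), as.integer(k),
                   as.integer(stride), as.integer(pad))
  nsp <- prod(od[1:3])
  y <- y + rep(b, each = nsp)
  list(y = array(y, dim = od), xm = xm, outdim = od, indim = dims,
       k = k, stride = stride, pad = pad)
}

convt3d_backward <- function(cache, W, dy) {
  k <- cache$k
  cout <- dim(W)[4L]
  cin <- dim(W)[5L]
  dycol <- cpp_im2col3(dy, as.integer(cache$outdim), as.integer(k),
                       as.integer(cache$stride), as.integer(cache$pad))
  dW <- array(dycol %*% cache$xm, dim = dim(W))
  db <- colSums(matrix(dy, ncol = cout))
  Wm <- matrix(W, nrow = k^3 * cout, ncol = cin)
  dxm <- crossprod(Wm, dycol)
  list(dW = dW, db = db, dx = array(t(dxm), dim = cache$indim))
}

leaky_relu_forward <- function(x, slope) {
  pos <- x > 0
  y <- x
  y[!pos] <- slope * y[!pos]
  list(y = y, pos = pos, slope = slope)
}

leaky_relu_backward <- function(cache, dy) {
  d <- dy
  d[!cache$pos] <- cache$slope * d[!cache$pos]
  d
}

clamp0_forward <- function(x) {
  pos <- x > 0
  list(y = x * pos, pos = pos)
}

clamp0_backward <- function(cache, dy) dy * cache$pos

#' Mean-absolute-deviation instance normalization
#'
#' Normalizes each channel of a volumetric activation by its spatial mean
#' and its mean absolute deviation (instead of the standard deviation), then
#' applies a learnable per-channel gain and offset:
#' `y = (x - mean(x)) / (mad(x) + eps) * gain + offset` with
#' `mad(x) = mean(|x - mean(x)|)`, statistics taken over spatial positions
#' per channel per instance. The deviation is deliberately not rescaled by
#' `sqrt(pi/2)` to mimic a standard deviation.
#'
#' @param x numeric 4D array `(x, y, z, channels)`.
#' @param gain,offset numeric vectors, one entry per channel.
#' @param eps small positive constant guarding constant channels.
#' @return numeric array shaped like `x`.
#' @export
mad_instance_norm <- function(x, gain = rep(1, dim(x)[4L]),
                              offset = rep(0, dim(x)[4L]), eps = 1e-5) {
  mad_in_forward(x, gain, offset, eps)$y
}

mad_in_forward <- function(x, gain, offset, eps) {
  d4 <- dim(x)
  n <- prod(d4[1:3])
  xm <- matrix(x, ncol = d4[4L])
  mu <- colMeans(xm)
  u <- xm - rep(mu, each = n)
  dev <- colMeans(abs(u)) + eps
  xhat <- u * rep(1 / dev, each = n)
  y <- xhat * rep(gain, each = n) + rep(offset, each = n)
  list(y = array(y, dim = d4), xhat = xhat, u = u, dev = dev,
       gain = gain, d4 = d4)
}

mad_in_backward <- function(cache, dy) {
  n <- prod(cache$d4[1:3])
  dym <- matrix(dy, ncol = cache$d4[4L])
  dgain <- colSums(dym * cache$xhat)
  doffset <- colSums(dym)
  s <- sign(cache$u)
  sbar <- colMeans(s)
  mdy <- colMeans(dym)
  mdx <- colMeans(dym * cache$xhat)
  core <- (dym - rep(mdy, each = n)) -
    (s - rep(sbar, each = n)) * rep(mdx, each = n)
  dx <- core * rep(cache$gain / cache$dev, each = n)
  list(dx = array(dx, dim = cache$d4), dgain = dgain, doffset = doffset)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1:3], da[4L] + db[4L]))
}

split_channels <- function(x, ca) {
  d4 <- dim(x)
  nsp <- prod(d4[1:3])
  xv <- as.vector(x)
  list(array(xv[seq_len(nsp * ca)], dim = c(d4[1:3], ca)),
       array(xv[-seq_len(nsp * ca)], dim = c(d4[1:3], d4[4L] - ca)))
}

# Adam with the CycleGAN-conventional constants; params and grads are
# parallel named lists of arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 2e-4,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}
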