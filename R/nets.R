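# 3D U-net generator and patchGAN discriminator.
#
# The generator encoder uses strided 4x4x4 convolutions only (no stride-1
# refinement blocks, no resize convolutions); the decoder mirrors it with
# stride-2 transposed convolutions and concatenating skip connections.
# Instance normalization uses the mean absolute deviation in place of the
# standard deviation. The final activation clamps negatives to zero and is
# linear above zero, so generated intensities are unbounded above.

#' Generator specification
#'
#' @param depth number of stride-2 down/up stages; input dims must be
#'   divisible by `2^depth`.
#' @param base_channels channels at the first encoder stage; doubled per
#'   stage, capped at `8 * base_channels`.
#' @param kernel spatial kernel edge (all stages).
#' @param leaky_slope negative slope of the encoder activations.
#' @param decoder_slope negative slope of the decoder activations (0 gives a
#'   plain rectifier).
#' @param use_instance_norm apply MAD instance normalization (all encoder
#'   stages after the first, and all decoder stages before the last).
#' @param eps normalization guard constant.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(depth = 2L, base_channels = 8L, kernel = 4L,
                           leaky_slope = 0.2, decoder_slope = 0,
                           use_instance_norm = TRUE, eps = 1e-5) {
  stopifnot(depth >= 1L, base_channels >= 1L, kernel >= 2L)
  ch <- pmin(base_channels * 2L^(seq_len(depth) - 1L), 8L * base_channels)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 channels = as.integer(ch),
                 kernel = as.integer(kernel),
                 leaky_slope = leaky_slope, decoder_slope = decoder_slope,
                 use_instance_norm = isTRUE(use_instance_norm), eps = eps),
            class = "generator_spec")
}

#' Discriminator specification
#'
#' A patchGAN stack given as a list of `(kernel, stride, channels)` stages.
#' The default — three stride-2 stages with 4-voxel kernels followed by a
#' stride-1 single-channel output stage with a 3-voxel kernel — has a
#' receptive field of 38 voxels per axis.
#'
#' @param layers list of numeric triples `(kernel, stride, out_channels)`.
#' @param leaky_slope negative slope of the activations (all but the last
#'   stage).
#' @param use_instance_norm normalize the middle stages (not the first, not
#'   the last), patchGAN convention.
#' @param eps normalization guard constant.
#' @return an object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(layers = list(c(4, 2, 8), c(4, 2, 16),
                                             c(4, 2, 32), c(3, 1, 1)),
                               leaky_slope = 0.2, use_instance_norm = TRUE,
                               eps = 1e-5) {
  stopifnot(length(layers) >= 1L)
  lay <- lapply(layers, function(l) {
    stopifnot(length(l) == 3L, l[1] >= 1, l[2] >= 1, l[3] >= 1)
    as.integer(l)
  })
  if (lay[[length(lay)]][3L] != 1L)
    stop("final discriminator stage must output one channel (patch scores)")
  structure(list(layers = lay, leaky_slope = leaky_slope,
                 use_instance_norm = isTRUE(use_instance_norm), eps = eps),
            class = "discriminator_spec")
}

#' Analytic receptive field of a discriminator stack
#'
#' One output unit sees `RF` input voxels per axis, via the recurrence
#' `RF_n = RF_{n-1} + (k_n - 1) * prod(strides before stage n)`.
#'
#' @param spec a [discriminator_spec()].
#' @return receptive field in voxels per axis (scalar).
#' @export
receptive_field <- function(spec) {
  rf <- 1L
  jump <- 1L
  for (l in spec$layers) {
    rf <- rf + (l[1L] - 1L) * jump
    jump <- jump * l[2L]
  }
  rf
}

conv_pad <- function(k) as.integer((k - 1L) %/% 2L)

init_w <- function(dims, sd = 0.02) array(stats::rnorm(prod(dims), 0, sd), dim = dims)

#' Build a generator
#'
#' Instantiates trainable parameters for a [generator_spec()]. Weights are
#' drawn `N(0, 0.02)` from the current RNG state; seed the RNG for
#' reproducible initialization.
#'
#' @param spec a [generator_spec()].
#' @return an object of class `generator` holding the spec and a named
#'   parameter list.
#' @export
build_generator <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  k <- spec$kernel
  ch <- spec$channels
  d <- spec$depth
  p <- list()
  cin <- 1L
  for (i in seq_len(d)) {
    p[[paste0("enc", i, "_W")]] <- init_w(c(k, k, k, cin, ch[i]))
    p[[paste0("enc", i, "_b")]] <- numeric(ch[i])
    if (i > 1L && spec$use_instance_norm) {
      p[[paste0("enc", i, "_g")]] <- rep(1, ch[i])
      p[[paste0("enc", i, "_o")]] <- rep(0, ch[i])
    }
    cin <- ch[i]
  }
  cur <- ch[d]
  for (j in rev(seq_len(d))) {
    if (j > 1L) {
      cout <- ch[j - 1L]
      p[[paste0("dec", j, "_W")]] <- init_w(c(k, k, k, cout, cur))
      p[[paste0("dec", j, "_b")]] <- numeric(cout)
      if (spec$use_instance_norm) {
        p[[paste0("dec", j, "_g")]] <- rep(1, cout)
        p[[paste0("dec", j, "_o")]] <- rep(0, cout)
      }
      cur <- 2L * cout                      # concat skip
    } else {
      p[[paste0("dec", j, "_W")]] <- init_w(c(k, k, k, 1L, cur))
      p[[paste0("dec", j, "_b")]] <- numeric(1L)
    }
  }
  structure(list(spec = spec, params = p), class = "generator")
}

check_gen_dims <- function(spec, dims) {
  if (any(dims[1:3] %% 2L^spec$depth != 0L))
    stop("input dims (", paste(dims[1:3], collapse = "x"),
         ") must be divisible by 2^depth = ", 2L^spec$depth)
}

# Forward pass; x is a (nx, ny, nz) array or (nx, ny, nz, 1). Returns the
# raw generated volume and, when keep_cache, everything backward needs.
generator_forward <- function(gen, x, keep_cache = FALSE) {
  spec <- gen$spec
  p <- gen$params
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  check_gen_dims(spec, dim(x))
  k <- spec$kernel
  pad <- conv_pad(k)
  d <- spec$depth
  cache <- list()
  h <- x
  skips <- vector("list", d)
  for (i in seq_len(d)) {
    cv <- conv3d_forward(h, p[[paste0("enc", i, "_W")]],
                         p[[paste0("enc", i, "_b")]], 2L, pad)
    h <- cv$y
    nrm <- NULL
    if (i > 1L && spec$use_instance_norm) {
      nrm <- mad_in_forward(h, p[[paste0("enc", i, "_g")]],
                            p[[paste0("enc", i, "_o")]], spec$eps)
      h <- nrm$y
    }
    act <- leaky_relu_forward(h, spec$leaky_slope)
    h <- act$y
    skips[[i]] <- h
    if (keep_cache) cache[[paste0("enc", i)]] <-
      list(conv = cv, norm = nrm, act = act)
  }
  for (j in rev(seq_len(d))) {
    if (j > 1L) {
      cv <- convt3d_forward(h, p[[paste0("dec", j, "_W")]],
                            p[[paste0("dec", j, "_b")]], 2L, pad)
      h <- cv$y
      nrm <- NULL
      if (spec$use_instance_norm) {
        nrm <- mad_in_forward(h, p[[paste0("dec", j, "_g")]],
                              p[[paste0("dec", j, "_o")]], spec$eps)
        h <- nrm$y
      }
      act <- leaky_relu_forward(h, spec$decoder_slope)
      h <- concat_channels(act$y, skips[[j - 1L]])
      if (keep_cache) cache[[paste0("dec", j)]] <-
        list(conv = cv, norm = nrm, act = act, ca = dim(act$y)[4L])
    } else {
      cv <- convt3d_forward(h, p[[paste0("dec", j, "_W")]],
                            p[[paste0("dec", j, "_b")]], 2L, pad)
      fin <- clamp0_forward(cv$y)
      h <- fin$y
      if (keep_cache) cache[[paste0("dec", j)]] <- list(conv = cv, fin = fin)
    }
  }
  out <- array(h, dim = dim(h)[1:3])
  if (keep_cache) list(out = out, cache = cache) else list(out = out)
}

# Backward pass through a cached generator forward; dout shaped like the
# output volume. Returns parameter gradients and the input gradient.
generator_backward <- function(gen, cache, dout) {
  spec <- gen$spec
  p <- gen$params
  d <- spec$depth
  grads <- list()
  cc <- cache[["dec1"]]
  dy <- clamp0_backward(cc$fin, array(dout, dim = dim(cc$fin$pos)))
  bw <- convt3d_backward(cc$conv, p[["dec1_W"]], dy)
  grads[["dec1_W"]] <- bw$dW
  grads[["dec1_b"]] <- bw$db
  dh <- bw$dx
  dskip <- vector("list", d)
  for (j in seq_len(d)[-1L]) {
    cc <- cache[[paste0("dec", j)]]
    sp <- split_channels(dh, cc$ca)
    dskip[[j - 1L]] <- sp[[2L]]
    dy <- leaky_relu_backward(cc$act, sp[[1L]])
    if (!is.null(cc$norm)) {
      nb <- mad_in_backward(cc$norm, dy)
      grads[[paste0("dec", j, "_g")]] <- nb$dgain
      grads[[paste0("dec", j, "_o")]] <- nb$doffset
      dy <- nb$dx
    }
    bw <- convt3d_backward(cc$conv, p[[paste0("dec", j, "_W")]], dy)
    grads[[paste0("dec", j, "_W")]] <- bw$dW
    grads[[paste0("dec", j, "_b")]] <- bw$db
    dh <- bw$dx
  }
  for (i in rev(seq_len(d))) {
    cc <- cache[[paste0("enc", i)]]
    if (!is.null(dskip[[i]])) dh <- dh + dskip[[i]]
    dy <- leaky_relu_backward(cc$act, dh)
    if (!is.null(cc$norm)) {
      nb <- mad_in_backward(cc$norm, dy)
      grads[[paste0("enc", i, "_g")]] <- nb$dgain
      grads[[paste0("enc", i, "_o")]] <- nb$doffset
      dy <- nb$dx
    }
    bw <- conv3d_backward(cc$conv, p[[paste0("enc", i, "_W")]], dy)
    grads[[paste0("enc", i, "_W")]] <- bw$dW
    grads[[paste0("enc", i, "_b")]] <- bw$db
    dh <- bw$dx
  }
  list(grads = grads, dx = dh)
}

#' Masked generation
#'
#' Runs a generator on a volume and multiplies the result by the original
#' brain mask, so every background voxel of the generated image is exactly
#' zero and brain structures outside the mask can never be hallucinated.
#'
#' @param gen a [build_generator()] object.
#' @param vol a [volume()] with a nonempty mask.
#' @return a [volume()] with the generated intensities under the input mask.
#' @export
masked_generate <- function(gen, vol) {
  stopifnot(inherits(gen, "generator"))
  if (is.null(vol$mask)) stop("masked_generate requires a brain mask")
  raw <- generator_forward(gen, vol$data)$out
  volume(raw * vol$mask, mask = vol$mask, spacing = vol$spacing,
         affine = vol$affine)
}

#' Build a discriminator
#'
#' @param spec a [discriminator_spec()].
#' @return an object of class `discriminator`.
#' @export
build_discriminator <- function(spec) {
  stopifnot(inherits(spec, "discriminator_spec"))
  p <- list()
  cin <- 1L
  nl <- length(spec$layers)
  for (i in seq_len(nl)) {
    l <- spec$layers[[i]]
    p[[paste0("l", i, "_W")]] <- init_w(c(l[1L], l[1L], l[1L], cin, l[3L]))
    p[[paste0("l", i, "_b")]] <- numeric(l[3L])
    if (i > 1L && i < nl && spec$use_instance_norm) {
      p[[paste0("l", i, "_g")]] <- rep(1, l[3L])
      p[[paste0("l", i, "_o")]] <- rep(0, l[3L])
    }
    cin <- l[3L]
  }
  structure(list(spec = spec, params = p), class = "discriminator")
}

discriminator_forward <- function(disc, x, keep_cache = FALSE) {
  spec <- disc$spec
  p <- disc$params
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  nl <- length(spec$layers)
  cache <- list()
  h <- x
  for (i in seq_len(nl)) {
    l <- spec$layers[[i]]
    cv <- conv3d_forward(h, p[[paste0("l", i, "_W")]],
                         p[[paste0("l", i, "_b")]], l[2L], conv_pad(l[1L]))
    h <- cv$y
    nrm <- NULL
    act <- NULL
    if (i > 1L && i < nl && spec$use_instance_norm) {
      nrm <- mad_in_forward(h, p[[paste0("l", i, "_g")]],
                            p[[paste0("l", i, "_o")]], spec$eps)
      h <- nrm$y
    }
    if (i < nl) {
      act <- leaky_relu_forward(h, spec$leaky_slope)
      h <- act$y
    }
    if (keep_cache) cache[[i]] <- list(conv = cv, norm = nrm, act = act)
  }
  out <- array(h, dim = dim(h)[1:3])
  if (keep_cache) list(out = out, cache = cache) else list(out = out)
}

discriminator_backward <- function(disc, cache, dout) {
  spec <- disc$spec
  p <- disc$params
  nl <- length(spec$layers)
  grads <- list()
  dh <- dout
  for (i in rev(seq_len(nl))) {
    cc <- cache[[i]]
    dy <- if (!is.null(cc$act)) {
      leaky_relu_backward(cc$act, array(dh, dim = dim(cc$act$pos)))
    } else array(dh, dim = dim(cc$conv$y))
    if (!is.null(cc$norm)) {
      nb <- mad_in_backward(cc$norm, dy)
      grads[[paste0("l", i, "_g")]] <- nb$dgain
      grads[[paste0("l", i, "_o")]] <- nb$doffset
      dy <- nb$dx
    }
    bw <- conv3d_backward(cc$conv, p[[paste0("l", i, "_W")]], dy)
    grads[[paste0("l", i, "_W")]] <- bw$dW
    grads[[paste0("l", i, "_b")]] <- bw$db
    dh <- bw$dx
  }
  list(grads = grads, dx = dh)
}

#' Empirical receptive field by gradient footprint
#'
#' Backpropagates from a single central output unit of a discriminator on a
#' cubic input and measures the extent of nonzero input gradients per axis.
#' For a correctly assembled stack this equals [receptive_field()] whenever
#' the input is large enough to contain the footprint. Instance
#' normalization statistics couple all spatial positions, so the probe
#' network is built with normalization disabled: the receptive field is a
#' property of the convolution stack, and normalization at frozen
#' statistics is a per-channel affine map that does not widen it.
#'
#' @param spec a [discriminator_spec()]; weights are drawn fresh from the
#'   current RNG state.
#' @param input_size input edge length in voxels.
#' @return integer vector of nonzero-gradient extents (one per axis).
#' @export
gradient_footprint <- function(spec, input_size = 64L) {
  probe_spec <- spec
  probe_spec$use_instance_norm <- FALSE
  disc <- build_discriminator(probe_spec)
  x <- array(stats::rnorm(input_size^3), dim = c(input_size, input_size,
                                                 input_size, 1L))
  fw <- discriminator_forward(disc, x, keep_cache = TRUE)
  od <- dim(fw$out)
  dout <- array(0, dim = od)
  ctr <- pmax(1L, od %/% 2L)
  dout[ctr[1L], ctr[2L], ctr[3L]] <- 1
  g <- discriminator_backward(disc, fw$cache, dout)$dx
  g3 <- array(g, dim = dim(g)[1:3])
  ext <- function(ax) {
    nz <- which(apply(abs(g3) > 1e-30, ax, any))
    if (!length(nz)) 0L else as.integer(max(nz) - min(nz) + 1L)
  }
  c(ext(1L), ext(2L), ext(3L))
}

#' Save / load network checkpoints
#'
#' A checkpoint records the spec, parameters, the seed and training step it
#' was produced under, in a single file.
#'
#' @param net a `generator` or `discriminator`.
#' @param path file path.
#' @param seed,step bookkeeping recorded in the checkpoint.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the network with `seed`/`step` attributes.
#' @export
save_checkpoint <- function(net, path, seed = NA_integer_, step = NA_integer_) {
  saveRDS(list(net = net, seed = seed, step = step,
               class = class(net)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- ck$net
  attr(net, "seed") <- ck$seed
  attr(net, "step") <- ck$step
  net
}
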