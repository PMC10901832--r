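# Network building blocks with hand-written reverse-mode gradients.
#
# Tensors are numeric arrays (nx, ny, nz, channels); complex tensors are
# lists with `re` and `im` arrays of identical shape (batch size is 1
# throughout, as in the training regime this package implements, so batch
# normalisation statistics are per-channel spatial statistics in training
# mode). Gradients w.r.t. complex quantities follow the convention
# d/d(Re) + i d/d(Im).

as_tensor4 <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

tensor_dims <- function(x) dim(x)[1:3]

# ---- real primitives --------------------------------------------------------

conv3_init <- function(cin, cout, kw, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (kw^3 * cin)) # He init for ReLU stacks
  list(
    w = array(stats::rnorm(kw^3 * cin * cout, sd = sd), c(kw, kw, kw, cin, cout)),
    b = rep(0, cout)
  )
}

conv3_fwd <- function(x, p) {
  d <- dim(x)
  kw <- dim(p$w)[1]
  cin <- dim(p$w)[4]
  cout <- dim(p$w)[5]
  stopifnot(d[4] == cin)
  y <- conv3d_fwd_cpp(x, p$w, p$b, as.integer(d[1:3]), kw, cin, cout)
  dim(y) <- c(d[1:3], cout)
  y
}

conv3_bwd <- function(x, p, gy) {
  d <- dim(x)
  kw <- dim(p$w)[1]
  cin <- dim(p$w)[4]
  cout <- dim(p$w)[5]
  gx <- conv3d_bwd_input_cpp(gy, p$w, as.integer(d[1:3]), kw, cin, cout)
  dim(gx) <- d
  gwb <- conv3d_bwd_weight_cpp(x, gy, as.integer(d[1:3]), kw, cin, cout)
  gw <- gwb$gw
  dim(gw) <- dim(p$w)
  list(gx = gx, gw = gw, gb = gwb$gb)
}

bn_init <- function(ch) {
  list(gamma = rep(1, ch), beta = rep(0, ch))
}

bn_state_init <- function(ch) {
  list(mean = rep(0, ch), var = rep(1, ch), n = 0L)
}

bn_fwd <- function(x, p, state, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  ch <- d[4]
  nvox <- prod(d[1:3])
  xm <- matrix(x, nvox, ch)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
    state$n <- state$n + 1L
  } else {
    mu <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  dim(y) <- d
  list(out = y, state = state,
       cache = list(xhat = xhat, invstd = invstd, dims = d, training = training))
}

bn_bwd <- function(p, cache, gy) {
  d <- cache$dims
  ch <- d[4]
  nvox <- prod(d[1:3])
  gym <- matrix(gy, nvox, ch)
  ggamma <- colSums(gym * cache$xhat)
  gbeta <- colSums(gym)
  if (cache$training) {
    gx <- sweep(
      gym - matrix(gbeta / nvox, nvox, ch, byrow = TRUE) -
        cache$xhat * matrix(ggamma / nvox, nvox, ch, byrow = TRUE),
      2, p$gamma * cache$invstd, "*"
    )
  } else {
    gx <- sweep(gym, 2, p$gamma * cache$invstd, "*")
  }
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

relu_fwd <- function(x) {
  y <- pmax(x, 0)
  dim(y) <- dim(x)
  y
}

relu_bwd <- function(x, gy) {
  gx <- gy * (x > 0)
  dim(gx) <- dim(x)
  gx
}

pool_fwd <- function(x) {
  d <- dim(x)
  r <- maxpool3d_cpp(x, as.integer(d[1:3]), d[4])
  out <- r$out
  dim(out) <- c(d[1:3] %/% 2L, d[4])
  list(out = out, argmax = r$argmax, n_in = length(x), dims = d)
}

pool_bwd <- function(cache, gy) {
  gx <- maxpool3d_bwd_cpp(gy, cache$argmax, cache$n_in)
  dim(gx) <- cache$dims
  gx
}

up_fwd <- function(x) {
  d <- dim(x)
  y <- upsample3d_cpp(x, as.integer(d[1:3]), d[4])
  dim(y) <- c(2L * d[1:3], d[4])
  y
}

up_bwd <- function(dims_coarse, ch, gy) {
  gx <- upsample3d_bwd_cpp(gy, as.integer(dims_coarse), ch)
  dim(gx) <- c(dims_coarse, ch)
  gx
}

# ---- complex primitives -----------------------------------------------------

#' Complex tensor constructor
#'
#' @param re,im Real arrays of identical shape `(nx, ny, nz, channels)` (a
#'   trailing channel axis is added to 3D arrays).
#' @return A list with elements `re` and `im`.
#' @export
complex_tensor <- function(re, im = array(0, dim(re))) {
  re <- as_tensor4(re)
  im <- as_tensor4(im)
  stopifnot(all(dim(re) == dim(im)), all(is.finite(re)), all(is.finite(im)))
  list(re = re, im = im)
}

#' Complex convolution parameters
#'
#' The complex kernel `W = A + iB` is stored as two real kernels plus a
#' complex bias. Initialisation draws `A` and `B` independently with the
#' variance halved relative to the real-valued scheme, so that `|W|` has the
#' variance the real init would give.
#'
#' @param cin,cout Channel counts.
#' @param kw Kernel width (odd; 3 in the full-scale architecture).
#' @return List with kernels `A`, `B` (`kw^3 x cin x cout`) and biases
#'   `br`, `bi`.
#' @export
complex_conv_params <- function(cin, cout, kw = 3) {
  sd <- sqrt(1 / (kw^3 * cin)) # half the real-valued He variance per part
  list(
    A = array(stats::rnorm(kw^3 * cin * cout, sd = sd), c(kw, kw, kw, cin, cout)),
    B = array(stats::rnorm(kw^3 * cin * cout, sd = sd), c(kw, kw, kw, cin, cout)),
    br = rep(0, cout), bi = rep(0, cout)
  )
}

#' Complex convolution
#'
#' For complex input `h = x + iy` and complex kernel `W = A + iB`,
#' `W * h = (A * x - B * y) + i (B * x + A * y)` built from four real
#' convolutions with shape-preserving zero padding.
#'
#' @param h A [complex_tensor()].
#' @param W Parameters from [complex_conv_params()].
#' @return A [complex_tensor()].
#' @export
complex_conv <- function(h, W) {
  pa <- list(w = W$A, b = W$br)
  pb0 <- list(w = W$B, b = rep(0, length(W$br)))
  re <- conv3_fwd(h$re, pa) - conv3_fwd(h$im, pb0)
  pa0 <- list(w = W$A, b = rep(0, length(W$br)))
  pbi <- list(w = W$B, b = W$bi)
  im <- conv3_fwd(h$re, pbi) + conv3_fwd(h$im, pa0)
  list(re = re, im = im)
}

complex_conv_bwd <- function(h, W, gre, gim) {
  pa <- list(w = W$A, b = W$br)
  pb <- list(w = W$B, b = W$bi)
  bra <- conv3_bwd(h$re, pa, gre) # d(A*x)
  bia <- conv3_bwd(h$im, pa, gim) # d(A*y)
  brb <- conv3_bwd(h$re, pb, gim) # d(B*x)
  bib <- conv3_bwd(h$im, pb, gre) # d(B*y), enters re with sign -1
  list(
    gA = bra$gw + bia$gw,
    gB = brb$gw - bib$gw,
    gbr = bra$gb,
    gbi = brb$gb,
    gre = bra$gx + brb$gx,
    gim = bia$gx - bib$gx
  )
}

#' Complex rectified linear unit
#'
#' Applies ReLU separately to the real and imaginary parts:
#' `CReLU(z) = ReLU(Re z) + i ReLU(Im z)`. Elementwise and idempotent.
#'
#' @param z A [complex_tensor()] (or complex array, returned as one).
#' @return A [complex_tensor()].
#' @export
crelu <- function(z) {
  if (is.complex(z)) z <- complex_tensor(Re(z), Im(z))
  list(re = relu_fwd(z$re), im = relu_fwd(z$im))
}

#' Complex batch normalisation (per-part variant)
#'
#' Standard batch normalisation applied independently to the real and the
#' imaginary part, each with its own learned scale and shift; running
#' statistics are tracked for inference mode.
#'
#' @param h A [complex_tensor()].
#' @param params List with `re` and `im` elements of `gamma`/`beta` vectors.
#' @param state Running statistics (list with `re`, `im`), see
#'   [complex_bn_state()].
#' @param training Use batch statistics and update `state` (TRUE), or the
#'   frozen running statistics (FALSE).
#' @return List with `out` (complex tensor), updated `state` and a backward
#'   `cache`.
#' @export
complex_batch_norm <- function(h, params, state, training = TRUE) {
  fr <- bn_fwd(h$re, params$re, state$re, training)
  fi <- bn_fwd(h$im, params$im, state$im, training)
  list(out = list(re = fr$out, im = fi$out),
       state = list(re = fr$state, im = fi$state),
       cache = list(re = fr$cache, im = fi$cache))
}

#' @rdname complex_batch_norm
#' @param ch Number of channels.
#' @export
complex_bn_state <- function(ch) {
  list(re = bn_state_init(ch), im = bn_state_init(ch))
}

complex_bn_params <- function(ch) {
  list(re = bn_init(ch), im = bn_init(ch))
}

# ---- model-correction network Gpsi -----------------------------------------

#' Build the k-space model-correction network
#'
#' Three complex convolutional layers acting on a one-channel complex k-space
#' volume: the first two layers (width `width`) are complex convolution
#' followed by complex batch normalisation and CReLU; the third maps back to
#' one channel with no activation, so the correction can output arbitrary
#' complex values. With `residual = TRUE` the network output is added to its
#' input and the final kernels start at zero, so the freshly built operator is
#' exactly the identity -- joint training then starts from the plain FFT
#' reconstruction.
#'
#' @param seed Integer seed for the parameter initialisation.
#' @param width Channel width of the two hidden layers (32 in the full-scale
#'   study architecture).
#' @param kw Kernel width (3).
#' @param residual Identity-plus-update parameterisation (see above).
#' @return A `pat_gnet` object.
#' @export
build_model_correction <- function(seed = 1, width = 32, kw = 3,
                                   residual = FALSE) {
  set.seed(seed)
  params <- list(
    c1 = complex_conv_params(1, width, kw),
    bn1 = complex_bn_params(width),
    c2 = complex_conv_params(width, width, kw),
    bn2 = complex_bn_params(width),
    c3 = complex_conv_params(width, 1, kw)
  )
  if (residual) {
    params$c3$A[] <- 0
    params$c3$B[] <- 0
  }
  structure(
    list(params = params,
         state = list(bn1 = complex_bn_state(width), bn2 = complex_bn_state(width)),
         width = width, kw = kw, residual = residual,
         fingerprint = sprintf("gnet/w%d/k%d/res%d", width, kw, as.integer(residual))),
    class = "pat_gnet"
  )
}

#' Apply the model-correction network to a complex k-volume
#'
#' @param net A `pat_gnet` from [build_model_correction()].
#' @param fvol Complex array `(nx, ny, nz)` (image k-space).
#' @param training Batch-statistics mode for the normalisation layers.
#' @param keep_cache Keep intermediate activations for [gnet_backward()].
#' @return List with complex array `out`, a `cache`, and the updated `state`
#'   (assign back to `net$state` during training).
#' @export
gnet_forward <- function(net, fvol, training = FALSE, keep_cache = FALSE) {
  h0 <- complex_tensor(array(Re(fvol), dim(fvol)), array(Im(fvol), dim(fvol)))
  p <- net$params
  st <- net$state
  h1 <- complex_conv(h0, p$c1)
  b1 <- complex_batch_norm(h1, p$bn1, st$bn1, training)
  a1 <- crelu(b1$out)
  h2 <- complex_conv(a1, p$c2)
  b2 <- complex_batch_norm(h2, p$bn2, st$bn2, training)
  a2 <- crelu(b2$out)
  h3 <- complex_conv(a2, p$c3)
  out <- complex(real = h3$re, imaginary = h3$im)
  dim(out) <- dim(fvol)
  if (net$residual) out <- out + fvol
  cache <- if (keep_cache) {
    list(h0 = h0, h1 = h1, b1 = b1$cache, a1 = a1, h2 = h2, b2 = b2$cache,
         a2 = a2)
  }
  list(out = out, cache = cache,
       state = list(bn1 = b1$state, bn2 = b2$state))
}

#' Backward pass of the model-correction network
#'
#' @param net A `pat_gnet`.
#' @param cache Cache from [gnet_forward()] with `keep_cache = TRUE`.
#' @param gout Complex array: loss gradient w.r.t. the network output
#'   (`d/dRe + i d/dIm`).
#' @return List with parameter gradients `grads` (same structure as
#'   `net$params`) and `gx`, the gradient w.r.t. the complex input.
#' @export
gnet_backward <- function(net, cache, gout) {
  p <- net$params
  d4 <- dim(cache$h0$re)
  gre <- array(Re(gout), d4)
  gim <- array(Im(gout), d4)
  g3 <- complex_conv_bwd(cache$a2, p$c3, gre, gim)
  ga2re <- relu_bwd(cache$a2$re, g3$gre) # a2 = relu(b2): mask by a2 > 0
  ga2im <- relu_bwd(cache$a2$im, g3$gim)
  b2r <- bn_bwd(p$bn2$re, cache$b2$re, ga2re)
  b2i <- bn_bwd(p$bn2$im, cache$b2$im, ga2im)
  g2 <- complex_conv_bwd(cache$a1, p$c2, b2r$gx, b2i$gx)
  ga1re <- relu_bwd(cache$a1$re, g2$gre)
  ga1im <- relu_bwd(cache$a1$im, g2$gim)
  b1r <- bn_bwd(p$bn1$re, cache$b1$re, ga1re)
  b1i <- bn_bwd(p$bn1$im, cache$b1$im, ga1im)
  g1 <- complex_conv_bwd(cache$h0, p$c1, b1r$gx, b1i$gx)
  grads <- list(
    c1 = list(A = g1$gA, B = g1$gB, br = g1$gbr, bi = g1$gbi),
    bn1 = list(re = list(gamma = b1r$ggamma, beta = b1r$gbeta),
               im = list(gamma = b1i$ggamma, beta = b1i$gbeta)),
    c2 = list(A = g2$gA, B = g2$gB, br = g2$gbr, bi = g2$gbi),
    bn2 = list(re = list(gamma = b2r$ggamma, beta = b2r$gbeta),
               im = list(gamma = b2i$ggamma, beta = b2i$gbeta)),
    c3 = list(A = g3$gA, B = g3$gB, br = g3$gbr, bi = g3$gbi)
  )
  gx <- complex(real = g1$gre, imaginary = g1$gim)
  dim(gx) <- d4[1:3]
  if (net$residual) gx <- gx + gout
  list(grads = grads, gx = gx)
}

# ---- post-processing U-Net --------------------------------------------------

#' Build the image-space post-processing U-Net
#'
#' Four scales (three 2x down/upsamplings): per scale two blocks of
#' convolution (3^3 kernels) -> batch normalisation -> ReLU, widths doubling
#' from `width` at the input scale to `8 * width` at the coarsest scale
#' (32 ... 256 in the full-scale study architecture); max-pool downsampling,
#' nearest-neighbour-plus-convolution upsampling, skip connections by channel
#' concatenation, and a final 1x1x1 convolution to one channel. Input volumes
#' whose sides are not divisible by 8 are zero-padded internally and cropped
#' on output.
#'
#' @param seed Integer seed for the initialisation.
#' @param width Base channel width (32 at full scale).
#' @return A `pat_unet` object.
#' @export
build_unet <- function(seed = 1, width = 32) {
  set.seed(seed)
  w <- width
  mk_block <- function(cin, cmid) {
    list(c1 = conv3_init(cin, cmid, 3), bn1 = bn_init(cmid),
         c2 = conv3_init(cmid, cmid, 3), bn2 = bn_init(cmid))
  }
  params <- list(
    e1 = mk_block(1, w),
    e2 = mk_block(w, 2 * w),
    e3 = mk_block(2 * w, 4 * w),
    e4 = mk_block(4 * w, 8 * w),
    u3 = list(c = conv3_init(8 * w, 4 * w, 3), bn = bn_init(4 * w)),
    d3 = mk_block(8 * w, 4 * w),
    u2 = list(c = conv3_init(4 * w, 2 * w, 3), bn = bn_init(2 * w)),
    d2 = mk_block(4 * w, 2 * w),
    u1 = list(c = conv3_init(2 * w, w, 3), bn = bn_init(w)),
    d1 = mk_block(2 * w, w),
    # near-zero output head: the freshly built operator maps to (almost) the
    # zero image, so training starts from the sparse-image baseline instead of
    # unit-scale noise
    out = conv3_init(w, 1, 1, sd = 1e-2)
  )
  widths <- c(w, 2 * w, 4 * w, 8 * w)
  state <- list(
    e1 = lapply(c(1, 1), function(i) bn_state_init(w)),
    e2 = lapply(c(1, 1), function(i) bn_state_init(2 * w)),
    e3 = lapply(c(1, 1), function(i) bn_state_init(4 * w)),
    e4 = lapply(c(1, 1), function(i) bn_state_init(8 * w)),
    u3 = bn_state_init(4 * w),
    d3 = lapply(c(1, 1), function(i) bn_state_init(4 * w)),
    u2 = bn_state_init(2 * w),
    d2 = lapply(c(1, 1), function(i) bn_state_init(2 * w)),
    u1 = bn_state_init(w),
    d1 = lapply(c(1, 1), function(i) bn_state_init(w))
  )
  structure(
    list(params = params, state = state, width = w, widths = widths,
         fingerprint = sprintf("unet/w%d/scales4", w)),
    class = "pat_unet"
  )
}

block_fwd <- function(x, p, st, training) {
  y1 <- conv3_fwd(x, p$c1)
  b1 <- bn_fwd(y1, p$bn1, st[[1]], training)
  a1 <- relu_fwd(b1$out)
  y2 <- conv3_fwd(a1, p$c2)
  b2 <- bn_fwd(y2, p$bn2, st[[2]], training)
  a2 <- relu_fwd(b2$out)
  list(out = a2, state = list(b1$state, b2$state),
       cache = list(x = x, b1 = b1$cache, a1 = a1, b2 = b2$cache, a2 = a2))
}

block_bwd <- function(p, cache, gy) {
  g2 <- relu_bwd(cache$a2, gy)
  bb2 <- bn_bwd(p$bn2, cache$b2, g2)
  cb2 <- conv3_bwd(cache$a1, p$c2, bb2$gx)
  g1 <- relu_bwd(cache$a1, cb2$gx)
  bb1 <- bn_bwd(p$bn1, cache$b1, g1)
  cb1 <- conv3_bwd(cache$x, p$c1, bb1$gx)
  list(
    gx = cb1$gx,
    grads = list(c1 = list(w = cb1$gw, b = cb1$gb),
                 bn1 = list(gamma = bb1$ggamma, beta = bb1$gbeta),
                 c2 = list(w = cb2$gw, b = cb2$gb),
                 bn2 = list(gamma = bb2$ggamma, beta = bb2$gbeta))
  )
}

upconv_fwd <- function(x, p, st, training) {
  u <- up_fwd(x)
  y <- conv3_fwd(u, p$c)
  b <- bn_fwd(y, p$bn, st, training)
  a <- relu_fwd(b$out)
  list(out = a, state = b$state,
       cache = list(dims_coarse = dim(x)[1:3], ch = dim(x)[4], u = u,
                    b = b$cache, a = a))
}

upconv_bwd <- function(p, cache, gy) {
  g <- relu_bwd(cache$a, gy)
  bb <- bn_bwd(p$bn, cache$b, g)
  cb <- conv3_bwd(cache$u, p$c, bb$gx)
  gx <- up_bwd(cache$dims_coarse, cache$ch, cb$gx)
  list(gx = gx,
       grads = list(c = list(w = cb$gw, b = cb$gb),
                    bn = list(gamma = bb$ggamma, beta = bb$gbeta)))
}

concat_ch <- function(a, b) {
  d <- dim(a)
  db <- dim(b)
  out <- array(0, c(d[1:3], d[4] + db[4]))
  out[, , , seq_len(d[4])] <- a
  out[, , , d[4] + seq_len(db[4])] <- b
  out
}

#' Apply the post-processing U-Net
#'
#' @param net A `pat_unet` from [build_unet()].
#' @param vol Real array `(nx, ny, nz)` (a reconstruction).
#' @param training Batch-statistics mode for the normalisation layers.
#' @param keep_cache Keep activations for [unet_backward()].
#' @return List with real array `out` (same shape as `vol`), a `cache`, and
#'   the updated `state`.
#' @export
unet_forward <- function(net, vol, training = FALSE, keep_cache = FALSE) {
  d0 <- dim(vol)
  dpad <- 8L * ceiling(d0 / 8)
  x <- array(0, c(dpad, 1L))
  x[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), 1] <- vol
  p <- net$params
  st <- net$state
  e1 <- block_fwd(x, p$e1, st$e1, training)
  p1 <- pool_fwd(e1$out)
  e2 <- block_fwd(p1$out, p$e2, st$e2, training)
  p2 <- pool_fwd(e2$out)
  e3 <- block_fwd(p2$out, p$e3, st$e3, training)
  p3 <- pool_fwd(e3$out)
  e4 <- block_fwd(p3$out, p$e4, st$e4, training)
  u3 <- upconv_fwd(e4$out, p$u3, st$u3, training)
  d3 <- block_fwd(concat_ch(u3$out, e3$out), p$d3, st$d3, training)
  u2 <- upconv_fwd(d3$out, p$u2, st$u2, training)
  d2 <- block_fwd(concat_ch(u2$out, e2$out), p$d2, st$d2, training)
  u1 <- upconv_fwd(d2$out, p$u1, st$u1, training)
  d1 <- block_fwd(concat_ch(u1$out, e1$out), p$d1, st$d1, training)
  y <- conv3_fwd(d1$out, p$out)
  out <- y[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), 1]
  dim(out) <- d0
  state <- list(e1 = e1$state, e2 = e2$state, e3 = e3$state, e4 = e4$state,
                u3 = u3$state, d3 = d3$state, u2 = u2$state, d2 = d2$state,
                u1 = u1$state, d1 = d1$state)
  cache <- if (keep_cache) {
    list(d0 = d0, dpad = dpad, e1 = e1$cache, p1 = p1, e2 = e2$cache, p2 = p2,
         e3 = e3$cache, p3 = p3, e4 = e4$cache, u3 = u3$cache, d3 = d3$cache,
         u2 = u2$cache, d2 = d2$cache, u1 = u1$cache, d1 = d1$cache,
         d1out = d1$out)
  }
  list(out = out, cache = cache, state = state)
}

#' Backward pass of the post-processing U-Net
#'
#' @param net A `pat_unet`.
#' @param cache Cache from [unet_forward()] with `keep_cache = TRUE`.
#' @param gout Real array: loss gradient w.r.t. the network output.
#' @return List with parameter gradients `grads` and input gradient `gx`.
#' @export
unet_backward <- function(net, cache, gout) {
  p <- net$params
  d0 <- cache$d0
  dpad <- cache$dpad
  gy <- array(0, c(dpad, 1L))
  gy[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), 1] <- gout
  cbo <- conv3_bwd(cache$d1out, p$out, gy)
  bd1 <- block_bwd(p$d1, cache$d1, cbo$gx)
  w <- net$width
  split1 <- function(g, wa) list(a = g[, , , seq_len(wa), drop = FALSE],
                                 b = g[, , , -seq_len(wa), drop = FALSE])
  s1 <- split1(bd1$gx, w)
  bu1 <- upconv_bwd(p$u1, cache$u1, s1$a)
  bd2 <- block_bwd(p$d2, cache$d2, bu1$gx)
  s2 <- split1(bd2$gx, 2L * w)
  bu2 <- upconv_bwd(p$u2, cache$u2, s2$a)
  bd3 <- block_bwd(p$d3, cache$d3, bu2$gx)
  s3 <- split1(bd3$gx, 4L * w)
  bu3 <- upconv_bwd(p$u3, cache$u3, s3$a)
  be4 <- block_bwd(p$e4, cache$e4, bu3$gx)
  ge3 <- pool_bwd(cache$p3, be4$gx) + s3$b
  be3 <- block_bwd(p$e3, cache$e3, ge3)
  ge2 <- pool_bwd(cache$p2, be3$gx) + s2$b
  be2 <- block_bwd(p$e2, cache$e2, ge2)
  ge1 <- pool_bwd(cache$p1, be2$gx) + s1$b
  be1 <- block_bwd(p$e1, cache$e1, ge1)
  gx <- be1$gx[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), 1]
  dim(gx) <- d0
  grads <- list(e1 = be1$grads, e2 = be2$grads, e3 = be3$grads,
                e4 = be4$grads, u3 = bu3$grads, d3 = bd3$grads,
                u2 = bu2$grads, d2 = bd2$grads, u1 = bu1$grads,
                d1 = bd1$grads, out = list(w = cbo$gw, b = cbo$gb))
  list(grads = grads, gx = gx)
}

#' Number of trainable parameters of a network
#'
#' @param net A `pat_gnet` or `pat_unet`.
#' @return Integer parameter count (complex kernels count their real and
#'   imaginary parts separately).
#' @export
count_parameters <- function(net) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      for (el in x) walk(el)
    } else {
      n <<- n + length(x)
    }
  }
  walk(net$params)
  n
}
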