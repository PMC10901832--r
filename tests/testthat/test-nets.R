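# brute-force 3D convolution oracle (zero padding, shape preserving)
conv3_brute <- function(x, w, b) {
  d <- dim(x)
  kw <- dim(w)[1]
  h <- kw %/% 2
  cin <- dim(w)[4]
  cout <- dim(w)[5]
  y <- array(0, c(d[1:3], cout))
  for (co in seq_len(cout)) {
    acc <- array(b[co], d[1:3])
    for (ci in seq_len(cin)) {
      for (kz in seq_len(kw)) for (ky in seq_len(kw)) for (kx in seq_len(kw)) {
        wv <- w[kx, ky, kz, ci, co]
        if (wv == 0) next
        for (z in seq_len(d[3])) {
          zz <- z + kz - h - 1
          if (zz < 1 || zz > d[3]) next
          for (y2 in seq_len(d[2])) {
            yy <- y2 + ky - h - 1
            if (yy < 1 || yy > d[2]) next
            for (x2 in seq_len(d[1])) {
              xx <- x2 + kx - h - 1
              if (xx < 1 || xx > d[1]) next
              acc[x2, y2, z] <- acc[x2, y2, z] + wv * x[xx, yy, zz, ci]
            }
          }
        }
      }
    }
    y[, , , co] <- acc
  }
  y
}

test_that("complex convolution reduces correctly in the real case", {
  set.seed(1)
  h <- complex_tensor(array(stats::rnorm(125), c(5, 5, 5, 1)))
  W <- complex_conv_params(1, 2)
  W$B[] <- 0
  W$bi[] <- 0
  out <- complex_conv(h, W)
  expect_true(all(out$im == 0))
})

test_that("1x1x1 complex convolution is complex multiplication", {
  h <- complex_tensor(array(2, c(1, 1, 1, 1)), array(3, c(1, 1, 1, 1)))
  W <- list(A = array(1, c(1, 1, 1, 1, 1)), B = array(1, c(1, 1, 1, 1, 1)),
            br = 0, bi = 0)
  out <- complex_conv(h, W)
  # (2 + 3i)(1 + i) = -1 + 5i
  expect_equal(as.numeric(out$re), -1)
  expect_equal(as.numeric(out$im), 5)
})

test_that("complex convolution matches the four-real-convolution oracle", {
  set.seed(7)
  h <- complex_tensor(array(stats::rnorm(125 * 2), c(5, 5, 5, 2)),
                      array(stats::rnorm(125 * 2), c(5, 5, 5, 2)))
  W <- complex_conv_params(2, 3)
  W$br <- stats::rnorm(3)
  W$bi <- stats::rnorm(3)
  out <- complex_conv(h, W)
  zero <- rep(0, 3)
  re_oracle <- conv3_brute(h$re, W$A, W$br) - conv3_brute(h$im, W$B, zero)
  im_oracle <- conv3_brute(h$re, W$B, W$bi) + conv3_brute(h$im, W$A, zero)
  expect_equal(out$re, re_oracle, tolerance = 1e-12)
  expect_equal(out$im, im_oracle, tolerance = 1e-12)
})

test_that("complex convolution is complex-linear (rotation by i)", {
  set.seed(8)
  h <- complex_tensor(array(stats::rnorm(64), c(4, 4, 4, 1)),
                      array(stats::rnorm(64), c(4, 4, 4, 1)))
  W <- complex_conv_params(1, 1)
  out <- complex_conv(h, W)
  # i * h = (-im) + i re; conv(i h) must equal i * conv(h) (bias-free)
  hi <- list(re = -h$im, im = h$re)
  outi <- complex_conv(hi, W)
  expect_equal(outi$re, -out$im, tolerance = 1e-12)
  expect_equal(outi$im, out$re, tolerance = 1e-12)
})

test_that("crelu identities hold exactly and crelu is idempotent", {
  z <- complex_tensor(array(c(1, -1, -1, 0), c(2, 2, 1, 1)),
                      array(c(2, 2, -2, 0), c(2, 2, 1, 1)))
  out <- crelu(z)
  expect_equal(as.numeric(out$re), c(1, 0, 0, 0))
  expect_equal(as.numeric(out$im), c(2, 2, 0, 0))
  again <- crelu(out)
  expect_identical(again, out)
  # nonexpansive per component
  expect_true(all(abs(out$re) <= abs(z$re) & abs(out$im) <= abs(z$im)))
})

test_that("complex batch norm standardises each part in training mode", {
  set.seed(9)
  h <- complex_tensor(array(stats::rnorm(4096, 5, 3), c(16, 16, 16, 1)),
                      array(stats::rnorm(4096, -2, 0.5), c(16, 16, 16, 1)))
  p <- patrecon:::complex_bn_params(1)
  st <- complex_bn_state(1)
  out <- complex_batch_norm(h, p, st, training = TRUE)
  expect_lt(abs(mean(out$out$re)), 1e-10)
  expect_lt(abs(mean(out$out$im)), 1e-10)
  expect_equal(stats::var(as.numeric(out$out$re)), 1, tolerance = 1e-2)
  # purely real input stays purely real
  hr <- complex_tensor(array(stats::rnorm(64), c(4, 4, 4, 1)))
  outr <- complex_batch_norm(hr, p, complex_bn_state(1), training = TRUE)
  expect_true(all(outr$out$im == 0))
})

test_that("inference-mode normalisation is bitwise deterministic", {
  set.seed(10)
  net <- build_model_correction(seed = 2, width = 3)
  fv <- array(complex(real = stats::rnorm(512), imaginary = stats::rnorm(512)),
              c(8, 8, 8))
  # populate running statistics once
  net$state <- gnet_forward(net, fv, training = TRUE)$state
  a <- gnet_forward(net, fv, training = FALSE)$out
  b <- gnet_forward(net, fv, training = FALSE)$out
  expect_identical(a, b)
})

test_that("model-correction parameter count matches the closed form", {
  w <- 32
  net <- build_model_correction(seed = 1, width = w)
  # per complex conv: 2 * 27 * cin * cout kernel weights + 2 * cout biases;
  # per complex BN: 2 parts * (gamma + beta) = 4 * channels
  expected <- (2 * 27 * 1 * w + 2 * w) + 4 * w +
    (2 * 27 * w * w + 2 * w) + 4 * w +
    (2 * 27 * w * 1 + 2)
  expect_equal(count_parameters(net), expected)
  out <- gnet_forward(net, array(0.5 + 0.1i, c(8, 8, 8)))$out
  expect_equal(dim(out), c(8, 8, 8))
  expect_true(all(is.finite(Mod(out))))
  # seeded rebuild is identical
  expect_identical(net$params, build_model_correction(seed = 1, width = w)$params)
})

test_that("U-Net has the stated scale widths and parameter count", {
  w <- 8
  net <- build_unet(seed = 3, width = w)
  expect_equal(net$widths, c(w, 2 * w, 4 * w, 8 * w))
  blk <- function(cin, cmid) {
    (27 * cin * cmid + cmid + 2 * cmid) + (27 * cmid * cmid + cmid + 2 * cmid)
  }
  upc <- function(cin, cout) 27 * cin * cout + cout + 2 * cout
  expected <- blk(1, w) + blk(w, 2 * w) + blk(2 * w, 4 * w) + blk(4 * w, 8 * w) +
    upc(8 * w, 4 * w) + blk(8 * w, 4 * w) +
    upc(4 * w, 2 * w) + blk(4 * w, 2 * w) +
    upc(2 * w, w) + blk(2 * w, w) +
    (1 * w * 1 + 1)
  expect_equal(count_parameters(net), expected)
  expect_identical(net$params, build_unet(seed = 3, width = w)$params)
})

test_that("U-Net preserves arbitrary (padded) input shapes", {
  net <- build_unet(seed = 4, width = 2)
  v <- array(stats::rnorm(16 * 16 * 8), c(16, 16, 8))
  out <- unet_forward(net, v)$out
  expect_equal(dim(out), dim(v))
  # non-multiple-of-8 shape is padded internally and cropped back
  v2 <- array(stats::rnorm(12 * 10 * 6), c(12, 10, 6))
  out2 <- unet_forward(net, v2)$out
  expect_equal(dim(out2), dim(v2))
  expect_true(all(is.finite(out2)))
})

test_that("network gradients match central finite differences", {
  set.seed(20)
  # small real U-Net on a 16^3 volume
  net <- build_unet(seed = 5, width = 2)
  v <- array(stats::rnorm(16^3, sd = 0.3), c(16, 16, 16))
  y <- array(stats::rnorm(16^3, sd = 0.3), c(16, 16, 16))
  fw <- unet_forward(net, v, training = TRUE, keep_cache = TRUE)
  gout <- 2 * (fw$out - y) / length(y)
  bw <- unet_backward(net, fw$cache, gout)
  lossfn <- function(n) loss_mse(unet_forward(n, v, training = TRUE)$out, y)
  for (probe in list(c("e2", "c1"), c("u3", "c"), c("d1", "c2"))) {
    idx <- 5
    ana <- bw$grads[[probe[1]]][[probe[2]]]$w[idx]
    eps <- 1e-5
    np <- net
    np$params[[probe[1]]][[probe[2]]]$w[idx] <-
      np$params[[probe[1]]][[probe[2]]]$w[idx] + eps
    nm <- net
    nm$params[[probe[1]]][[probe[2]]]$w[idx] <-
      nm$params[[probe[1]]][[probe[2]]]$w[idx] - eps
    num <- (lossfn(np) - lossfn(nm)) / (2 * eps)
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-10), 1e-3)
  }
})
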