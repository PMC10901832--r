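matched_grid64 <- function() make_grid(64, 64, 32, 1.06e-4, 64, 1.06e-4 / 1500)

test_that("weighting factor honours its conventions", {
  g <- make_grid(16, 16, 8, 1.06e-4, 16, 1.06e-4 / 1500)
  B <- weighting_factor(g, 1500)
  ax <- grid_k_axes(g)
  expect_equal(dim(B), c(16, 16, 16))
  # omega = 0 plane is zero everywhere
  expect_true(all(B[, , which(ax$omega == 0)] == 0))
  # evanescent samples are zero; propagating samples are positive and finite
  for (j in which(ax$omega != 0)) {
    k2 <- outer(ax$kx^2, ax$ky^2, "+")
    evan <- (ax$omega[j] / 1500)^2 < k2
    expect_true(all(B[, , j][evan] == 0))
    expect_true(all(B[, , j][!evan] > 0))
    expect_true(all(is.finite(B[, , j])))
  }
})

test_that("data_to_kspace handles zero and constant records", {
  g <- make_grid(8, 8, 4, 1e-4, 8, 1e-4 / 1500)
  zero <- sensor_data(array(0, c(8, 8, 8)), g)
  fd <- data_to_kspace(zero, 1500, g)
  expect_true(all(fd$values == 0) && fd$dc == 0)
  const <- sensor_data(array(1, c(8, 8, 8)), g)
  fdc <- data_to_kspace(const, 1500, g)
  # all weighted energy at DC is rerouted through the separate dc slot
  expect_true(all(fdc$values == 0))
  expect_gt(Mod(fdc$dc), 0)
})

test_that("kspace_to_image inverts the forward 3D FFT and is real for Hermitian input", {
  set.seed(1)
  v <- array(stats::rnorm(8 * 8 * 8), c(8, 8, 8))
  f <- stats::fft(v)
  expect_equal(kspace_to_image(f), v, tolerance = 1e-12)
  # explicitly Hermitian-symmetrised random spectrum -> exactly real image
  z <- array(complex(real = stats::rnorm(512), imaginary = stats::rnorm(512)),
             c(8, 8, 8))
  rev_idx <- c(1, 8:2)
  zs <- z + Conj(z[rev_idx, rev_idx, rev_idx]) # z(k) + conj(z(-k)): Hermitian
  img <- stats::fft(zs, inverse = TRUE) / length(zs)
  expect_lt(max(abs(Im(img))), 1e-10 * max(abs(Re(img))))
})

test_that("Parseval relation holds for the discrete transforms", {
  set.seed(2)
  x <- array(stats::rnorm(8 * 8 * 8), c(8, 8, 8))
  X <- stats::fft(x)
  expect_equal(sum(Mod(X)^2), length(x) * sum(x^2), tolerance = 1e-10)
})

test_that("matched-grid interpolation is exact injection on the uniform column", {
  g <- matched_grid64()
  c0 <- 1500
  ax <- grid_k_axes(g)
  # on the kx = ky = 0 column the queries omega* = c0*|kz| hit omega nodes
  wq <- patrecon:::dispersion_omega(g, c0)[1, 1, ]
  hits <- vapply(wq, function(w) min(abs(ax$omega - w)), numeric(1))
  expect_true(all(hits < 1e-6))
})

test_that("out-of-band dispersion queries return zero", {
  g <- make_grid(8, 8, 8, 1e-4, 8, 1e-4 / 1500)
  set.seed(3)
  vals <- array(complex(real = stats::rnorm(512), imaginary = stats::rnorm(512)),
                c(8, 8, 8))
  fd <- structure(list(values = vals, dc = 0 + 0i, c0 = 1500, grid = g),
                  class = "pat_kdata")
  # with c0 grossly too large every query overshoots the omega band
  f <- interp_to_image_kspace(fd, g, c0 = 1500 * 100)
  f[1, 1, 1] <- 0
  expect_true(all(f == 0))
})

test_that("interpolation adjoint satisfies the inner-product identity", {
  g <- make_grid(8, 8, 8, 1e-4, 8, 0.8e-4 / 1500)
  set.seed(4)
  n <- 8 * 8 * 8
  vals <- array(complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)),
                c(8, 8, 8))
  fd <- structure(list(values = vals, dc = 0.3 + 0.1i, c0 = 1500, grid = g),
                  class = "pat_kdata")
  f <- interp_to_image_kspace(fd)
  u <- array(complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)),
             c(8, 8, 8))
  adj <- patrecon:::interp_to_image_kspace_adjoint(u, g, 1500)
  # treat complex tensors as real pairs: <u, A v> = <A' u, v>
  ip <- function(a, b) sum(Re(a) * Re(b) + Im(a) * Im(b))
  lhs <- ip(u, f)
  rhs <- ip(adj$values, vals) + ip(adj$dc, fd$dc)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("round trip is near-exact for a laterally uniform smooth phantom", {
  g <- matched_grid64()
  prof <- exp(-0.5 * ((0:(g$nz - 1) - 14) / 3)^2)
  slab <- array(rep(prof, each = g$nx * g$ny), c(g$nx, g$ny, g$nz))
  rec <- fft_planar_recon(forward_fft_homogeneous(slab, 1500, g), 1500, g)
  expect_lt(sqrt(sum((rec - slab)^2) / sum(slab^2)), 1e-4)
})

test_that("learned operator with no networks equals the plain reconstruction", {
  g <- make_grid(16, 16, 16, 1.06e-4, 16, 1.06e-4 / 1500)
  p0 <- gaussian_ball(g, 7, 2)
  rec0 <- fft_planar_recon(forward_fft_homogeneous(p0, 1500, g), 1500, g)
  lr <- learned_recon_operator(forward_fft_homogeneous(p0, 1500, g), 1500, g)
  expect_equal(lr$output, rec0, tolerance = 1e-14)
  # residual-initialised model correction is the exact identity too
  gnet <- build_model_correction(seed = 1, width = 4, residual = TRUE)
  lr2 <- learned_recon_operator(forward_fft_homogeneous(p0, 1500, g), 1500, g,
                                gnet = gnet)
  expect_equal(lr2$output, rec0, tolerance = 1e-12)
})

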