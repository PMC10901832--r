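matched_grid <- function(n = 32L, c0 = 1500) {
  make_grid(n, n, n / 2L, 1.06e-4, n, 1.06e-4 / c0)
}

test_that("pseudospectral scheme is exact for a single homogeneous mode", {
  c0 <- 1500
  dx <- 1.06e-4
  g <- make_grid(16, 16, 16, dx, 24, 0.4 * dx / c0)
  kx <- 2 * 2 * pi / (16 * dx)
  x <- (0:15) * dx
  p0 <- array(cos(kx * x), c(16, 16, 16))
  rec <- forward_pseudospectral(p0, c0, g, cfl = 1, sponge_width = 0)
  analytic <- outer(cos(kx * x), cos(c0 * kx * (0:23) * g$dt))
  expect_lt(max(abs(rec$values[, 1, ] - analytic)), 1e-12)
})

test_that("both forward models are linear and map zero to zero", {
  g <- matched_grid(24)
  zero <- array(0, c(g$nx, g$ny, g$nz))
  expect_true(all(forward_fft_homogeneous(zero, 1500, g)$values == 0))
  expect_true(all(forward_pseudospectral(zero, 1500, g, sponge_width = 4)$values == 0))
  p0 <- gaussian_ball(g, 6, 2)
  gf1 <- forward_fft_homogeneous(p0, 1500, g)$values
  gf3 <- forward_fft_homogeneous(3.5 * p0, 1500, g)$values
  expect_equal(gf3, 3.5 * gf1, tolerance = 1e-12)
  gp1 <- forward_pseudospectral(p0, 1500, g, sponge_width = 4)$values
  gp3 <- forward_pseudospectral(3.5 * p0, 1500, g, sponge_width = 4)$values
  expect_equal(gp3, 3.5 * gp1, tolerance = 1e-12)
})

test_that("laterally uniform slab follows the 1D d'Alembert solution", {
  c0 <- 1500
  g <- matched_grid(32)
  z0 <- 7
  prof <- exp(-0.5 * ((0:(g$nz - 1) - z0) / 2)^2)
  p0 <- array(rep(prof, each = g$nx * g$ny), c(g$nx, g$ny, g$nz))
  gp <- forward_pseudospectral(p0, c0, g, sponge_width = 10,
                               sponge_axes = "z")
  tr <- gp$values[1, 1, ]
  # arrival: half-amplitude Gaussian pulse centred at t = z0 / c (in samples,
  # with dt = dx / c, that is sample index z0 + 1)
  expect_equal(which.max(tr), z0 + 1)
  expect_equal(max(tr), 0.5, tolerance = 0.02)
  expect_equal(tr[z0 + 1 + 4], 0.5 * exp(-0.5 * (4 / 2)^2), tolerance = 0.02)
  # the spectral forward reproduces the same record
  gf <- forward_fft_homogeneous(p0, c0, g)
  expect_lt(max(abs(gf$values[1, 1, ] - tr)), 0.02)
})

test_that("time of flight of a point-like source matches z0 / c0", {
  g <- matched_grid(32)
  z0 <- 9
  p0 <- gaussian_ball(g, z0, 1.5)
  gf <- forward_fft_homogeneous(p0, 1500, g)
  tr <- gf$values[g$nx / 2 + 1, g$ny / 2 + 1, ]
  # the epicentral trace is an N-shaped pulse whose centre zero crossing marks
  # the arrival of the shell centre at t = z0 / c0
  ipk <- which.max(tr)
  itr <- which.min(tr)
  seg <- tr[ipk:itr]
  cross <- ipk + which(seg[-1] * seg[-length(seg)] <= 0)[1] - 1
  expect_lt(abs(cross - (z0 + 1)), 2)
})

test_that("spectral and pseudospectral forwards agree on a smooth phantom", {
  g <- matched_grid(32)
  p0 <- gaussian_ball(g, 7, 2.5)
  gf <- forward_fft_homogeneous(p0, 1500, g)
  gp <- forward_pseudospectral(p0, 1500, g, sponge_width = 24,
                               sponge_axes = "z", sponge_clearance = 12)
  rel <- sqrt(sum((gf$values - gp$values)^2) / sum(gp$values^2))
  expect_lt(rel, 0.06) # frozen few-percent cross-validation tolerance
})

test_that("pseudospectral solver self-converges under grid refinement", {
  c0 <- 1500
  dx <- 2.12e-4
  g1 <- make_grid(16, 16, 16, dx, 12, dx / c0)
  prof <- exp(-0.5 * ((0:15 - 6) / 2.5)^2)
  p1 <- array(rep(prof, each = 256), c(16, 16, 16))
  g2 <- make_grid(32, 32, 32, dx / 2, 23, dx / (2 * c0))
  prof2 <- exp(-0.5 * ((0:31 / 2 - 6) / 2.5)^2)
  p2 <- array(rep(prof2, each = 1024), c(32, 32, 32))
  r1 <- forward_pseudospectral(p1, c0, g1, cfl = 0.5, sponge_width = 0)
  r2 <- forward_pseudospectral(p2, c0, g2, cfl = 0.5, sponge_width = 0)
  coarse_from_fine <- r2$values[seq(1, 32, 2), seq(1, 32, 2), seq(1, 23, 2)]
  rel <- sqrt(sum((coarse_from_fine - r1$values)^2) / sum(r1$values^2))
  expect_lt(rel, 0.05)
})

test_that("measurement noise follows the fraction-of-peak model", {
  g <- matched_grid(24)
  p0 <- gaussian_ball(g, 6, 2)
  gc <- forward_fft_homogeneous(p0, 1500, g)
  expect_identical(add_measurement_noise(gc, 0)$values, gc$values)
  gn <- add_measurement_noise(gc, 0.01, seed = 2)
  expect_equal(gn$noise_sigma, 0.01 * max(gc$values))
  # large-sample empirical standard deviation within 1% of sigma
  resid <- gn$values - gc$values
  expect_gt(length(resid), 1e4)
  expect_lt(abs(stats::sd(resid) / gn$noise_sigma - 1), 0.01)
  # seeded reproducibility
  gn2 <- add_measurement_noise(gc, 0.01, seed = 2)
  expect_identical(gn$values, gn2$values)
})

test_that("time reversal reconstructs structure from its own solver's data", {
  g <- make_grid(32, 32, 16, 1.06e-4, 32, 1.06e-4 / 1500)
  zero_g <- sensor_data(array(0, c(32, 32, 32)), g)
  expect_true(all(time_reversal(zero_g, 1500, g) == 0))
  p0 <- gaussian_ball(g, 7, 2)
  gp <- forward_pseudospectral(p0, 1500, g, sponge_width = 12,
                               sponge_clearance = 6)
  tr <- time_reversal(gp, 1500, g, sponge_width = 12, sponge_clearance = 6)
  expect_true(all(tr >= 0))
  margin <- psnr(tr, p0) - psnr(0 * p0, p0)
  expect_gt(margin, 2.5) # frozen margin over an empty image
  expect_gt(stats::cor(as.numeric(tr), as.numeric(p0)), 0.7)
})

test_that("time reversal and FFT reconstruction agree at matched sound speed", {
  g <- make_grid(32, 32, 16, 1.06e-4, 32, 1.06e-4 / 1500)
  p0 <- gaussian_ball(g, 7, 2)
  gf <- forward_fft_homogeneous(p0, 1500, g)
  tr <- time_reversal(gf, 1500, g, sponge_width = 16, sponge_clearance = 8)
  fr <- pmax(fft_planar_recon(gf, 1500, g), 0)
  expect_lt(abs(psnr(tr, p0) - psnr(fr, p0)), 6) # frozen cross-method bound
})
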