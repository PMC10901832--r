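# Acoustic forward models and the time-reversal baseline.
#
# Two forward solvers are provided:
#  * forward_fft_homogeneous(): the exact spectral forward for homogeneous
#    media, constructed as the inverse of the planar FFT reconstruction
#    (fft_planar_recon) on the shared k-space conventions of fftrecon.R.
#  * forward_pseudospectral(): a k-space corrected Fourier pseudospectral
#    solver of (d_tt - c(x)^2 Lap) p = 0 for arbitrary sound-speed maps.

#' Sensor data container
#'
#' Pressure time series recorded on the `z = 0` detector plane.
#'
#' @param values Real array `(nx, ny, nt)`.
#' @param grid A [make_grid()] grid.
#' @param noise_sigma Realised noise standard deviation (0 for clean data).
#' @return A `pat_sensor_data` object.
#' @export
sensor_data <- function(values, grid, noise_sigma = 0) {
  assert_grid(grid)
  stopifnot(is.numeric(values), all(dim(values) == c(grid$nx, grid$ny, grid$nt)))
  if (!all(is.finite(values))) stop("sensor data must be finite", call. = FALSE)
  structure(list(values = values, grid = grid, noise_sigma = noise_sigma),
            class = "pat_sensor_data")
}

#' @export
print.pat_sensor_data <- function(x, ...) {
  cat(sprintf("<pat_sensor_data> %d x %d detectors, %d samples, max |g| = %.3g, noise sigma = %.3g\n",
              x$grid$nx, x$grid$ny, x$grid$nt, max(abs(x$values)), x$noise_sigma))
  invisible(x)
}

#' Exact spectral forward model for a homogeneous medium
#'
#' Maps an initial pressure to the planar sensor record through the
#' homogeneous dispersion relation `omega = c0 |k|`. In every detector
#' wavenumber column the recorded field is the free-space mode sum
#' `g(k1, k2, t) = sum_kz p0_hat(k1, k2, kz) cos(c0 |k| t)`, with the depth
#' spectrum sampled finely by zero-padding (`zpad`) so that periodic ghost
#' copies lie beyond the record; the record's DFT is evaluated in closed form
#' with one-sided Dirichlet kernels, which makes the operator exact for the
#' truncated record, including the spectral leakage a finite-duration
#' measurement really has. The amplitude convention follows the wave
#' equation's symmetric split of the initial pressure (a laterally uniform
#' slab arrives at half amplitude).
#'
#' On a matched grid (`dt = dx / c0`) the subsequent [fft_planar_recon()]
#' inverts this operator exactly on the laterally uniform column; for generic
#' smooth phantoms the reconstruction recovers everything except the loss
#' intrinsic to planar limited-view detection (grazing modes near the
#' dispersion cone `kz ~ 0`) and modes beyond the sampled frequency band.
#'
#' @param p0 An [initial_pressure()] object or a real `(nx, ny, nz)` array.
#' @param c0 True speed of sound of the medium (m/s), positive scalar.
#' @param grid A [make_grid()] grid.
#' @param zpad Integer zero-padding factor of the depth axis (>= 2; default 4)
#'   controlling how far periodic ghost copies are pushed beyond the record.
#' @return A [sensor_data()] object (clean; `noise_sigma = 0`).
#' @export
forward_fft_homogeneous <- function(p0, c0, grid, zpad = 4L) {
  if (inherits(p0, "pat_p0")) p0 <- p0$values
  assert_grid(grid)
  if (!is.numeric(c0) || length(c0) != 1L || c0 <= 0) {
    stop("c0 must be a positive scalar", call. = FALSE)
  }
  stopifnot(all(dim(p0) == c(grid$nx, grid$ny, grid$nz)))
  nxy <- grid$nx * grid$ny
  nzf <- as.integer(zpad) * grid$nz

  pz <- array(0, dim = c(grid$nx, grid$ny, nzf))
  pz[, , seq_len(grid$nz)] <- p0
  P <- fft3(pz)
  dim(P) <- c(nxy, nzf)

  ax <- grid_k_axes(grid)
  k2perp <- c(outer(ax$kx^2, ax$ky^2, "+"))
  kzf <- fft_omega_axis(nzf, grid$dx)
  D <- fwd_record_dft_cpp(P, k2perp, kzf, c0, grid$dt, grid$nt)
  dim(D) <- c(grid$nx, grid$ny, grid$nt)
  g <- Re(stats::fft(D, inverse = TRUE)) / length(D)
  sensor_data(g, grid)
}

# --- pseudospectral solver ---------------------------------------------------

#' Pseudospectral acoustic forward solver
#'
#' Integrates the lossless scalar wave equation
#' `(d_tt - c(x)^2 Lap) p = 0`, `p(x, 0) = p0`, `d_t p(x, 0) = 0`,
#' with a Fourier-spectral Laplacian and second-order leapfrog time stepping.
#' A k-space correction factor `sinc^2(c_ref |k| dt_int / 2)` (with `c_ref`
#' the maximum sound speed) multiplies the spectral Laplacian, which makes the
#' scheme exact in homogeneous media and unconditionally stable. Outgoing
#' waves are absorbed by a cosine-tapered sponge layer on the domain faces;
#' the domain is padded by the sponge width on every padded face, in
#' particular above the sensor plane, which emulates a transparent detector in
#' acoustic contact with the tissue. Pressure on the `z = 0` plane is recorded
#' at the grid's `dt` (the internal step is an integer subdivision
#' `dt_int = dt / ceil(dt / (cfl * dx / max(c)))`, so output samples land
#' exactly on the requested time grid).
#'
#' @param p0 An [initial_pressure()] object or real `(nx, ny, nz)` array.
#' @param sos A sound-speed map: positive scalar, `pat_sos` object, or real
#'   `(nx, ny, nz)` array (m/s).
#' @param grid A [make_grid()] grid.
#' @param cfl CFL number of the internal step. Default 1 for homogeneous media
#'   (where the corrected scheme is exact at any step) and 0.3 for
#'   heterogeneous maps.
#' @param sponge_width Sponge thickness in voxels (also the padding depth);
#'   0 disables absorption (periodic domain, useful for convergence tests).
#' @param sponge_axes Axes on which to pad and absorb, subset of
#'   `c("x", "y", "z")`. Laterally periodic runs (`"z"` only) are useful for
#'   comparisons against the laterally periodic spectral forward.
#' @param sponge_clearance Clear (undamped) padding voxels between the domain
#'   and the absorbing ramp, so the ramp does not graze the recorded field.
#' @param sponge_strength Peak per-step damping exponent of the ramp; small
#'   values reduce the impedance mismatch (and hence reflections) at the cost
#'   of weaker absorption per pass.
#' @return A [sensor_data()] object.
#' @export
forward_pseudospectral <- function(p0, sos, grid, cfl = NULL,
                                   sponge_width = 24,
                                   sponge_axes = c("x", "y", "z"),
                                   sponge_clearance = 12L,
                                   sponge_strength = 0.15) {
  if (inherits(p0, "pat_p0")) p0 <- p0$values
  assert_grid(grid)
  stopifnot(all(dim(p0) == c(grid$nx, grid$ny, grid$nz)))
  cvals <- sos_values(sos, grid)
  homogeneous <- length(cvals) == 1L
  cmax <- max(cvals)
  if (cmax <= 0 || any(cvals <= 0)) stop("sound speed must be positive", call. = FALSE)
  if (is.null(cfl)) cfl <- if (homogeneous) 1 else 0.3
  if (cfl <= 0 || cfl > 1) stop("cfl must be in (0, 1]", call. = FALSE)

  st <- pseudospectral_setup(p0, cvals, grid, cfl, sponge_width, sponge_axes,
                             sponge_clearance, sponge_strength)
  p <- st$p0pad
  g <- array(0, dim = c(grid$nx, grid$ny, grid$nt))
  g[, , 1] <- p[st$ix, st$iy, st$sensor_z]

  lap <- function(p) Re(stats::fft(st$lapk * stats::fft(p), inverse = TRUE)) / length(p)
  pm <- p
  pn <- p
  nsteps <- (grid$nt - 1L) * st$r
  for (step in seq_len(nsteps)) {
    if (step == 1L) {
      # symmetric first leapfrog step implements d_t p(0) = 0
      pnew <- pn + 0.5 * st$c2dt2 * lap(pn)
    } else {
      pnew <- 2 * pn - pm + st$c2dt2 * lap(pn)
    }
    pnew <- pnew * st$mask
    pm <- pn * st$mask
    pn <- pnew
    if (step %% st$r == 0L) {
      j <- step %/% st$r + 1L
      g[, , j] <- pn[st$ix, st$iy, st$sensor_z]
      if (!all(is.finite(pn[1, 1, ]))) {
        stop("pseudospectral solver produced non-finite values at step ", step,
             call. = FALSE)
      }
    }
  }
  if (!all(is.finite(g))) stop("pseudospectral solver diverged", call. = FALSE)
  sensor_data(g, grid)
}

sos_values <- function(sos, grid) {
  if (inherits(sos, "pat_sos")) sos <- sos$values
  if (is.numeric(sos) && length(sos) == 1L) return(sos)
  stopifnot(is.numeric(sos), all(dim(sos) == c(grid$nx, grid$ny, grid$nz)))
  sos
}

pseudospectral_setup <- function(p0, cvals, grid, cfl, sponge_width,
                                 sponge_axes, sponge_clearance = 12L,
                                 sponge_strength = 0.15) {
  cmax <- max(cvals)
  r <- max(1L, as.integer(ceiling(grid$dt / (cfl * grid$dx / cmax) - 1e-9)))
  dti <- grid$dt / r
  sw <- as.integer(sponge_width)
  pad <- if (sw > 0) sw + as.integer(sponge_clearance) else 0L
  padx <- if ("x" %in% sponge_axes) pad else 0L
  pady <- if ("y" %in% sponge_axes) pad else 0L
  padz <- if ("z" %in% sponge_axes) pad else 0L
  dims <- c(grid$nx + 2L * padx, grid$ny + 2L * pady, grid$nz + 2L * padz)
  ix <- seq_len(grid$nx) + padx
  iy <- seq_len(grid$ny) + pady
  iz <- seq_len(grid$nz) + padz
  p0pad <- array(0, dims)
  p0pad[ix, iy, iz] <- p0
  if (length(cvals) == 1L) {
    c2 <- cvals^2
  } else {
    cpad <- array(0, dims)
    cpad[ix, iy, iz] <- cvals
    # replicate edges into the padding
    if (padx > 0) {
      for (i in seq_len(padx)) {
        cpad[i, , ] <- cpad[padx + 1L, , ]
        cpad[dims[1] - i + 1L, , ] <- cpad[dims[1] - padx, , ]
      }
    }
    if (pady > 0) {
      for (i in seq_len(pady)) {
        cpad[, i, ] <- cpad[, pady + 1L, ]
        cpad[, dims[2] - i + 1L, ] <- cpad[, dims[2] - pady, ]
      }
    }
    if (padz > 0) {
      for (i in seq_len(padz)) {
        cpad[, , i] <- cpad[, , padz + 1L]
        cpad[, , dims[3] - i + 1L] <- cpad[, , dims[3] - padz]
      }
    }
    c2 <- cpad^2
  }
  kx <- fft_omega_axis(dims[1], grid$dx)
  ky <- fft_omega_axis(dims[2], grid$dx)
  kz <- fft_omega_axis(dims[3], grid$dx)
  k2 <- outer(outer(kx^2, ky^2, "+"), kz^2, "+")
  k <- sqrt(k2)
  arg <- cmax * k * dti / 2
  sinc2 <- ifelse(k == 0, 1, (sin(arg) / pmax(arg, .Machine$double.xmin))^2)
  sinc2[k == 0] <- 1
  lapk <- -k2 * sinc2
  mask <- if (sw > 0 && (padx + pady + padz) > 0) {
    sponge_mask_axes(dims, sw, padx > 0, pady > 0, padz > 0, sponge_strength)
  } else {
    1
  }
  list(
    p0pad = p0pad, lapk = lapk, c2dt2 = c2 * dti^2, mask = mask,
    ix = ix, iy = iy, sensor_z = padz + 1L, r = r, dti = dti, dims = dims
  )
}

sponge_mask_axes <- function(dims, width, on_x, on_y, on_z, strength = 0.5) {
  ramp <- function(n, on) {
    prof <- rep(0, n)
    if (on && width > 0) {
      i <- seq_len(min(width, n))
      rr <- (width - i + 1) / width
      prof[i] <- 0.5 * (1 - cos(pi * rr))
      prof[n - i + 1] <- pmax(prof[n - i + 1], 0.5 * (1 - cos(pi * rr)))
    }
    prof
  }
  px <- ramp(dims[1], on_x); py <- ramp(dims[2], on_y); pz <- ramp(dims[3], on_z)
  s <- array(px, dims) +
    array(rep(py, each = dims[1]), dims) +
    array(rep(pz, each = dims[1] * dims[2]), dims)
  exp(-strength * pmin(s, 1))
}

#' Add Gaussian measurement noise to sensor data
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `noise_frac * max(g)` (maximum over the whole clean array); the built-in
#' scenarios use the 1%-of-peak model, `noise_frac = 0.01`.
#'
#' @param g A [sensor_data()] object.
#' @param noise_frac Noise standard deviation as a fraction of the data
#'   maximum (>= 0).
#' @param seed Integer seed for reproducibility (optional).
#' @return A [sensor_data()] object with `noise_sigma` recorded.
#' @export
add_measurement_noise <- function(g, noise_frac, seed = NULL) {
  stopifnot(inherits(g, "pat_sensor_data"))
  if (!is.numeric(noise_frac) || length(noise_frac) != 1L || noise_frac < 0) {
    stop("noise_frac must be a nonnegative scalar", call. = FALSE)
  }
  if (noise_frac == 0) return(g)
  if (!is.null(seed)) set.seed(seed)
  sigma <- noise_frac * max(g$values)
  g$values <- g$values + stats::rnorm(length(g$values), sd = sigma)
  g$noise_sigma <- sigma
  g
}

#' Time-reversal reconstruction
#'
#' Runs the pseudospectral integrator backward in time from a zero field,
#' enforcing the time-reversed sensor data as a Dirichlet condition on the
#' detector plane at every internal step, and returns the field at `t = 0`
#' clipped to nonnegative values.
#'
#' @param g A [sensor_data()] object.
#' @param sos Sound speed assumed in the reconstruction: scalar, `pat_sos`
#'   object or `(nx, ny, nz)` array (m/s).
#' @param grid A [make_grid()] grid (taken from `g` if omitted).
#' @param cfl,sponge_width,sponge_axes,sponge_clearance,sponge_strength As in
#'   [forward_pseudospectral()].
#' @return Real array `(nx, ny, nz)`: the reconstructed initial pressure.
#' @export
time_reversal <- function(g, sos, grid = NULL, cfl = NULL, sponge_width = 24,
                          sponge_axes = c("x", "y", "z"),
                          sponge_clearance = 12L, sponge_strength = 0.15) {
  stopifnot(inherits(g, "pat_sensor_data"))
  if (is.null(grid)) grid <- g$grid
  assert_grid(grid)
  cvals <- sos_values(sos, grid)
  homogeneous <- length(cvals) == 1L
  if (is.null(cfl)) cfl <- if (homogeneous) 1 else 0.3
  st <- pseudospectral_setup(array(0, c(grid$nx, grid$ny, grid$nz)), cvals,
                             grid, cfl, sponge_width, sponge_axes,
                             sponge_clearance, sponge_strength)
  lap <- function(p) Re(stats::fft(st$lapk * stats::fft(p), inverse = TRUE)) / length(p)

  # time-reversed data, linearly interpolated to the internal steps
  grev <- g$values[, , grid$nt:1, drop = FALSE]
  nsteps <- (grid$nt - 1L) * st$r
  gq <- function(step) {
    # step in 0..nsteps maps onto reversed sample axis 1..nt
    pos <- step / st$r + 1
    j <- min(max(floor(pos), 1), grid$nt - 1L)
    w <- pos - j
    (1 - w) * grev[, , j] + w * grev[, , j + 1L]
  }

  p <- array(0, st$dims)
  pm <- array(0, st$dims)
  p[st$ix, st$iy, st$sensor_z] <- gq(0)
  for (s in seq_len(nsteps)) {
    pnew <- 2 * p - pm + st$c2dt2 * lap(p)
    pnew <- pnew * st$mask
    pnew[st$ix, st$iy, st$sensor_z] <- gq(s)
    pm <- p * st$mask
    p <- pnew
  }
  if (!all(is.finite(p))) stop("time reversal diverged", call. = FALSE)
  out <- p[st$ix, st$iy, st$sensor_z - 1L + seq_len(grid$nz)]
  pmax(out, 0)
}

#' Gaussian-ball test phantom
#'
#' A smooth isotropic Gaussian initial pressure centred laterally, at a given
#' depth; used by round-trip and depth-scaling tests.
#'
#' @param grid A [make_grid()] grid.
#' @param depth_vox Centre depth in voxels below the sensor plane.
#' @param sigma_vox Gaussian standard deviation in voxels.
#' @return Real array `(nx, ny, nz)` with maximum 1.
#' @export
gaussian_ball <- function(grid, depth_vox, sigma_vox = 2.5) {
  assert_grid(grid)
  x <- seq_len(grid$nx) - 1 - (grid$nx / 2)
  y <- seq_len(grid$ny) - 1 - (grid$ny / 2)
  z <- seq_len(grid$nz) - 1 - depth_vox
  e <- exp(-0.5 * outer(outer(x^2, y^2, "+"), z^2, "+") / sigma_vox^2)
  e / max(e)
}
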