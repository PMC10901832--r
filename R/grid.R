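#' Spatial/temporal discretisation for planar-sensor photoacoustics
#'
#' A `pat_grid` holds the shared discretisation used by phantoms, solvers and
#' the Fourier reconstruction: an isotropic voxel grid of `nx x ny x nz`
#' voxels with spacing `dx` (m), and `nt` time samples with interval `dt` (s).
#' The detector is the full `z = 0` face (the "top" of the domain); `z`
#' increases with depth into the medium. Voxel centres sit at `(i - 1) * dx`
#' for 1-based index `i`, so the first voxel layer is on the sensor plane,
#' and time samples sit at `t_j = (j - 1) * dt` (the record starts at `t = 0`).
#'
#' Wavenumber and frequency axes are angular and FFT-ordered:
#' `k_i = 2 * pi * m / (N * dx)` for `m = 0, 1, ..., N/2 - 1, -N/2, ..., -1`,
#' and `omega = 2 * pi * f` analogously on the time axis, so the dispersion
#' relation of the wave equation reads literally `omega = c * |k|`.
#'
#' @param nx,ny,nz Voxel counts per axis (each >= 2).
#' @param dx Isotropic voxel spacing in metres.
#' @param nt Number of time samples (>= 2).
#' @param dt Temporal sampling interval in seconds.
#' @return An object of class `pat_grid`.
#' @examples
#' # the full-scale study grid: 120 x 120 x 40 voxels at 0.106 mm, 200 time
#' # samples at 20 MHz
#' g <- make_grid(120, 120, 40, 1.06e-4, 200, 5e-8)
#' @export
make_grid <- function(nx, ny, nz, dx, nt, dt) {
  for (v in list(nx = nx, ny = ny, nz = nz, nt = nt)) {
    if (!is.numeric(v) || length(v) != 1L || v < 2 || v != round(v)) {
      stop("grid sizes nx, ny, nz, nt must be integers >= 2", call. = FALSE)
    }
  }
  if (!is.numeric(dx) || length(dx) != 1L || dx <= 0) {
    stop("dx must be a positive scalar (metres)", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a positive scalar (seconds)", call. = FALSE)
  }
  structure(
    list(
      nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
      dx = as.numeric(dx), nt = as.integer(nt), dt = as.numeric(dt),
      sensor_plane = 0L
    ),
    class = "pat_grid"
  )
}

#' @export
print.pat_grid <- function(x, ...) {
  cat(sprintf(
    "<pat_grid> %d x %d x %d voxels @ %.4g mm, %d time samples @ %.4g MHz\n",
    x$nx, x$ny, x$nz, x$dx * 1e3, x$nt, 1e-6 / x$dt
  ))
  invisible(x)
}

is_grid <- function(x) inherits(x, "pat_grid")

assert_grid <- function(grid) {
  if (!is_grid(grid)) stop("expected a 'pat_grid' object", call. = FALSE)
  invisible(grid)
}

#' FFT-ordered angular frequency axis
#'
#' Returns the angular wavenumber (or frequency) axis for an `n`-point FFT
#' with sample spacing `d`: values `2 * pi * m / (n * d)` with FFT ordering
#' `m = 0, ..., n/2 - 1, -n/2, ..., -1` (for even `n`).
#'
#' @param n Number of samples.
#' @param d Sample spacing.
#' @return Numeric vector of length `n`.
#' @export
fft_omega_axis <- function(n, d) {
  m <- c(seq(0L, floor((n - 1) / 2)), seq(-ceiling((n - 1) / 2), -1L))
  2 * pi * m / (n * d)
}

#' Wavenumber and frequency axes of a grid
#'
#' @param grid A `pat_grid`.
#' @return List with FFT-ordered angular axes `kx`, `ky`, `kz` (rad/m) and
#'   `omega` (rad/s).
#' @export
grid_k_axes <- function(grid) {
  assert_grid(grid)
  list(
    kx = fft_omega_axis(grid$nx, grid$dx),
    ky = fft_omega_axis(grid$ny, grid$dx),
    kz = fft_omega_axis(grid$nz, grid$dx),
    omega = fft_omega_axis(grid$nt, grid$dt)
  )
}
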