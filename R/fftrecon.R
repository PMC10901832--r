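# Fourier-domain reconstruction for a planar sensor, decomposed into stages so
# a learned k-space correction can be inserted between the dispersion-relation
# interpolation and the inverse FFT.
#
# Conventions (fixed once, shared by the forward operator in wave.R):
#  * All discrete transforms are R's fft(); the time axis of fft(g) therefore
#    uses the kernel exp(-i*omega*t). Under that kernel the data node at
#    angular frequency omega carries the image mode at
#    kz = sign(omega) * sqrt((omega/c0)^2 - kx^2 - ky^2),
#    so the image mode (kx, ky, kz) is read from the data at the signed query
#    frequency omega* = sign(kz) * c0 * |k|. Using the signed bijection
#    (rather than folding onto omega >= 0) keeps the up/down-going information
#    separate and avoids wrapping a mirror ghost into the imaging depth.
#  * The weighting factor B carries the Jacobian c0^2*kz/(2*omega) of the
#    dispersion map; the remaining constant 4*dt/dx converts between the
#    unnormalised discrete transforms of g and p0.

fft3 <- function(x) stats::fft(x)
ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Dispersion-relation query frequencies for every image k-space node
#'
#' For each image-grid wavenumber `k = (kx, ky, kz)` returns the signed
#' angular frequency `omega* = sign(kz) * c0 * |k|` at which the planar
#' measurement spectrum holds that mode (`+c0*|k|` on the `kz = 0` plane).
#'
#' @param grid A [make_grid()] grid.
#' @param c0 Reconstruction speed of sound (m/s).
#' @return Numeric array `(nx, ny, nz)` of query frequencies (rad/s).
#' @keywords internal
dispersion_omega <- function(grid, c0) {
  ax <- grid_k_axes(grid)
  k2perp <- outer(ax$kx^2, ax$ky^2, "+")
  out <- array(0, dim = c(grid$nx, grid$ny, grid$nz))
  for (m in seq_len(grid$nz)) {
    kz <- ax$kz[m]
    s <- if (kz < 0) -1 else 1 # omega* = sign(kz)*c|k|; kz = 0 -> +c|k|
    out[, , m] <- s * c0 * sqrt(k2perp + kz^2)
  }
  out
}

#' Weighting factor of the planar FFT reconstruction
#'
#' The Jacobian-like weight applied to the transformed sensor data before the
#' dispersion-relation interpolation:
#' `B = c0^2 * kz_eff / (2 * |omega|)` with
#' `kz = sqrt((omega/c0)^2 - kx^2 - ky^2)`. By convention `B = 0` on the
#' `omega = 0` plane and in the evanescent region
#' `(omega/c0)^2 < kx^2 + ky^2`; on the propagating side the `1/kz` Jacobian
#' divergence at the cone (grazing incidence) is capped at its value one
#' frequency cell away from the cone, `kz_floor = sqrt(2 |omega| domega) / c0`,
#' the natural finite-record limit, so `B` stays finite and positive there.
#'
#' @param grid A [make_grid()] grid.
#' @param c0 Speed of sound used in the reconstruction (m/s), positive.
#' @return Numeric array `(nx, ny, nt)` over the `(k1, k2, omega)` data grid.
#' @export
weighting_factor <- function(grid, c0) {
  assert_grid(grid)
  if (!is.numeric(c0) || length(c0) != 1L || c0 <= 0) {
    stop("c0 must be a positive scalar", call. = FALSE)
  }
  ax <- grid_k_axes(grid)
  k2perp <- outer(ax$kx^2, ax$ky^2, "+")
  domega <- 2 * pi / (grid$nt * grid$dt)
  B <- array(0, dim = c(grid$nx, grid$ny, grid$nt))
  for (j in seq_len(grid$nt)) {
    w <- ax$omega[j]
    if (w == 0) next
    kz2 <- (w / c0)^2 - k2perp
    prop <- kz2 >= 0
    kz <- sqrt(pmax(kz2, 0))
    # finite-record cap of the 1/kz Jacobian divergence at the cone:
    # one frequency cell dω away from the cone, kz = sqrt(2|ω|dω)/c
    kz_floor <- sqrt(2 * abs(w) * domega) / c0
    Bj <- c0^2 * pmax(kz, kz_floor) / (2 * abs(w))
    Bj[!prop] <- 0
    B[, , j] <- Bj
  }
  B
}

#' Transform sensor data to weighted data k-space
#'
#' Applies the 2D FFT over the detector plane and the FFT along time, then
#' multiplies by the [weighting_factor()] (and the fixed transform constant
#' `4 * dt / dx`). The DC component (`k = 0`, `omega = 0`), which the weighting
#' zeroes by convention, is carried separately so the constant image mode
#' remains recoverable.
#'
#' @param g A [sensor_data()] object or a real `(nx, ny, nt)` array.
#' @param c0 Reconstruction speed of sound (m/s).
#' @param grid A [make_grid()] grid (taken from `g` if it is sensor data).
#' @return A `pat_kdata` object: complex `values` over `(k1, k2, omega)`,
#'   scalar `dc`, plus `c0` and the grid.
#' @export
data_to_kspace <- function(g, c0, grid = NULL) {
  if (inherits(g, "pat_sensor_data")) {
    if (is.null(grid)) grid <- g$grid
    g <- g$values
  }
  assert_grid(grid)
  stopifnot(is.numeric(g), all(dim(g) == c(grid$nx, grid$ny, grid$nt)))
  if (!all(is.finite(g))) stop("sensor data contains non-finite values", call. = FALSE)
  D <- fft3(g)
  B <- weighting_factor(grid, c0)
  structure(
    list(
      values = D * B * (4 * grid$dt / grid$dx),
      dc = D[1, 1, 1] * 2 * c0 * grid$dt / grid$dx,
      c0 = c0, grid = grid
    ),
    class = "pat_kdata"
  )
}

# Sorted-axis bookkeeping shared by the interpolation and its adjoint, and by
# the forward operator's inverse placement: the FFT-ordered omega axis is
# uniform once sorted, so bracketing nodes follow from arithmetic.
omega_sorted_index <- function(grid) {
  omega <- fft_omega_axis(grid$nt, grid$dt)
  ord <- order(omega)
  list(ord = ord, min = omega[ord[1]], d = 2 * pi / (grid$nt * grid$dt))
}

#' Interpolate weighted data k-space onto the image k-grid
#'
#' For every image node `(kx, ky, kz)` evaluates the weighted data spectrum at
#' the signed dispersion frequency `omega* = sign(kz) * c0 * |k|` by linear
#' interpolation along the omega axis of its `(k1, k2)` column; queries beyond
#' the sampled omega range give 0. The map is linear in the data, so the
#' adjoint used during training is exact (see
#' [interp_to_image_kspace_adjoint()]).
#'
#' @param fdata A `pat_kdata` object from [data_to_kspace()].
#' @param grid A [make_grid()] grid; defaults to the one stored in `fdata`.
#' @param c0 Speed of sound (m/s); defaults to the one stored in `fdata`.
#' @return Complex array `(nx, ny, nz)` on the image k-grid.
#' @export
interp_to_image_kspace <- function(fdata, grid = fdata$grid, c0 = fdata$c0) {
  stopifnot(inherits(fdata, "pat_kdata"))
  assert_grid(grid)
  os <- omega_sorted_index(grid)
  nxy <- grid$nx * grid$ny
  # reorder the omega axis once so brackets are index arithmetic
  Ms <- fdata$values[, , os$ord, drop = FALSE]
  dim(Ms) <- c(nxy, grid$nt)
  wstar <- dispersion_omega(grid, c0)
  f <- array(0 + 0i, dim = c(grid$nx, grid$ny, grid$nz))
  dim(f) <- c(nxy, grid$nz)
  cols <- seq_len(nxy)
  for (m in seq_len(grid$nz)) {
    pos <- (wstar[, , m] - os$min) / os$d + 1
    j <- floor(pos)
    w <- pos - j
    ok <- j >= 1 & j <= grid$nt - 1
    jj <- which(ok)
    if (!length(jj)) next
    f[jj, m] <- (1 - w[jj]) * Ms[cbind(cols[jj], j[jj])] +
      w[jj] * Ms[cbind(cols[jj], j[jj] + 1L)]
  }
  dim(f) <- c(grid$nx, grid$ny, grid$nz)
  f[1, 1, 1] <- fdata$dc
  f
}

#' Adjoint of [interp_to_image_kspace()]
#'
#' Scatters a gradient on the image k-grid back onto the data k-space nodes
#' with the same linear-interpolation weights; used for reverse-mode gradient
#' propagation through the reconstruction.
#'
#' @param gf Complex array `(nx, ny, nz)`: gradient w.r.t. the image k-volume,
#'   stored as `d/d(Re) + i * d/d(Im)`.
#' @param grid,c0 As in [interp_to_image_kspace()].
#' @return List with complex array `values` `(nx, ny, nt)` and scalar `dc`.
#' @keywords internal
interp_to_image_kspace_adjoint <- function(gf, grid, c0) {
  os <- omega_sorted_index(grid)
  nxy <- grid$nx * grid$ny
  wstar <- dispersion_omega(grid, c0)
  gdc <- gf[1, 1, 1]
  gf[1, 1, 1] <- 0
  dim(gf) <- c(nxy, grid$nz)
  G <- matrix(0 + 0i, nxy, grid$nt)
  cols <- seq_len(nxy)
  for (m in seq_len(grid$nz)) {
    pos <- (wstar[, , m] - os$min) / os$d + 1
    j <- floor(pos)
    w <- pos - j
    jj <- which(j >= 1 & j <= grid$nt - 1)
    if (!length(jj)) next
    i1 <- cbind(cols[jj], j[jj])
    i2 <- cbind(cols[jj], j[jj] + 1L)
    G[i1] <- G[i1] + (1 - w[jj]) * gf[jj, m]
    G[i2] <- G[i2] + w[jj] * gf[jj, m]
  }
  # undo the sorted ordering
  V <- array(0 + 0i, dim = c(grid$nx, grid$ny, grid$nt))
  dim(V) <- c(nxy, grid$nt)
  V[, os$ord] <- G
  dim(V) <- c(grid$nx, grid$ny, grid$nt)
  list(values = V, dc = gdc)
}

#' Inverse FFT from the image k-grid to a real volume
#'
#' Inverse 3D FFT of the (possibly network-corrected) image k-volume; the real
#' part is returned. No nonnegativity clipping is applied here -- clipping is
#' an evaluation-time choice.
#'
#' @param fvol Complex array `(nx, ny, nz)`.
#' @return Real array `(nx, ny, nz)`.
#' @export
kspace_to_image <- function(fvol) {
  if (!all(is.finite(Re(fvol))) || !all(is.finite(Im(fvol)))) {
    stop("k-space volume contains non-finite values", call. = FALSE)
  }
  Re(ifft3(fvol))
}

# gradient of kspace_to_image: for y = Re(ifft3(f)), dL/df = fft3(dL/dy)/N
# (stored as d/dRe + i * d/dIm).
kspace_to_image_adjoint <- function(gy) {
  fft3(gy) / length(gy)
}

#' Planar-sensor FFT reconstruction
#'
#' The unlearned Fourier-domain reconstruction: transform the sensor data,
#' weight, interpolate via the dispersion relation onto the image k-grid, and
#' inverse-FFT. Deterministic; output may contain negative values.
#'
#' @param g A [sensor_data()] object or a real `(nx, ny, nt)` array.
#' @param c0 Speed of sound assumed in the reconstruction (m/s).
#' @param grid A [make_grid()] grid (taken from `g` if it is sensor data).
#' @return Real array `(nx, ny, nz)`: the reconstructed initial pressure.
#' @examples
#' grid <- make_grid(32, 32, 16, 1e-4, 32, 1e-4 / 1500)
#' p0 <- gaussian_ball(grid, depth_vox = 8, sigma_vox = 2.5)
#' g <- forward_fft_homogeneous(p0, 1500, grid)
#' rec <- fft_planar_recon(g, 1500, grid)
#' @export
fft_planar_recon <- function(g, c0, grid = NULL) {
  if (inherits(g, "pat_sensor_data") && is.null(grid)) grid <- g$grid
  fdata <- data_to_kspace(g, c0, grid)
  fvol <- interp_to_image_kspace(fdata)
  kspace_to_image(fvol)
}

#' Learned reconstruction operator
#'
#' The full trainable composition: weighted data k-space -> dispersion
#' interpolation -> complex k-space model-correction network -> inverse FFT ->
#' image-space post-processing network. With both networks `NULL` (or built as
#' identities) this equals [fft_planar_recon()]. Every stage supports
#' reverse-mode gradients; see [learned_recon_backward()].
#'
#' @param g A [sensor_data()] object or a real `(nx, ny, nt)` array.
#' @param c0 Reconstruction speed of sound (m/s).
#' @param grid A [make_grid()] grid.
#' @param gnet A model-correction network from [build_model_correction()], or
#'   `NULL` for the identity.
#' @param unet A post-processing network from [build_unet()], or `NULL` for
#'   the identity.
#' @param training Logical; use batch statistics (TRUE) or running statistics
#'   (FALSE) in the networks' normalisation layers.
#' @param keep_cache Logical; retain the per-stage caches needed for a
#'   subsequent backward pass.
#' @return List with the reconstructed volume `output` and (if `keep_cache`)
#'   a `cache` list.
#' @export
learned_recon_operator <- function(g, c0, grid = NULL, gnet = NULL, unet = NULL,
                                   training = FALSE, keep_cache = FALSE) {
  if (inherits(g, "pat_sensor_data") && is.null(grid)) grid <- g$grid
  assert_grid(grid)
  fdata <- data_to_kspace(g, c0, grid)
  fvol <- interp_to_image_kspace(fdata)
  cache <- list(grid = grid, c0 = c0)
  if (!is.null(gnet)) {
    gf <- gnet_forward(gnet, fvol, training = training,
                       keep_cache = keep_cache)
    fcorr <- gf$out
    cache$gnet <- gf$cache
  } else {
    fcorr <- fvol
  }
  if (!all(dim(fcorr) == c(grid$nx, grid$ny, grid$nz))) {
    stop("model-correction stage changed the k-volume shape", call. = FALSE)
  }
  vol <- kspace_to_image(fcorr)
  if (!is.null(unet)) {
    uf <- unet_forward(unet, vol, training = training, keep_cache = keep_cache)
    out <- uf$out
    cache$unet <- uf$cache
  } else {
    out <- vol
  }
  if (!all(dim(out) == c(grid$nx, grid$ny, grid$nz))) {
    stop("post-processing stage changed the volume shape", call. = FALSE)
  }
  list(output = out, cache = if (keep_cache) cache else NULL)
}

#' Backward pass of the learned reconstruction operator
#'
#' Propagates a gradient w.r.t. the reconstructed volume back through the
#' post-processing network, the inverse FFT and the model-correction network.
#'
#' @param gout Real array `(nx, ny, nz)`: gradient of the loss w.r.t. the
#'   operator output.
#' @param cache Cache returned by [learned_recon_operator()] with
#'   `keep_cache = TRUE`.
#' @param gnet,unet The networks used in the forward pass (or `NULL`).
#' @return List with `gnet_grads`, `unet_grads` (parameter gradients, `NULL`
#'   where no network was used) and `gdata` (gradient w.r.t. the weighted
#'   data k-space, a list with `values` and `dc`).
#' @export
learned_recon_backward <- function(gout, cache, gnet = NULL, unet = NULL) {
  unet_grads <- NULL
  gvol <- gout
  if (!is.null(unet)) {
    ub <- unet_backward(unet, cache$unet, gout)
    unet_grads <- ub$grads
    gvol <- ub$gx
  }
  gfcorr <- kspace_to_image_adjoint(gvol)
  gnet_grads <- NULL
  gfvol <- gfcorr
  if (!is.null(gnet)) {
    gb <- gnet_backward(gnet, cache$gnet, gfcorr)
    gnet_grads <- gb$grads
    gfvol <- gb$gx
  }
  gdata <- interp_to_image_kspace_adjoint(gfvol, cache$grid, cache$c0)
  list(gnet_grads = gnet_grads, unet_grads = unet_grads, gdata = gdata)
}
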