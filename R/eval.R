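# Image-quality metrics (PSNR, 3D SSIM) and the experiment harnesses: the
# method-comparison table and the PSNR-vs-sound-speed sweep.

#' Peak signal-to-noise ratio
#'
#' `10 log10(max(reference)^2 / MSE)` in dB, with the peak taken from the true
#' initial pressure (not a global constant). An exact match returns the capped
#' sentinel 200 dB.
#'
#' @param recon,reference Real arrays of identical shape; `reference` must not
#'   be all zero.
#' @return PSNR in dB.
#' @export
psnr <- function(recon, reference) {
  if (!all(dim(recon) == dim(reference))) {
    stop("psnr: shape mismatch", call. = FALSE)
  }
  if (max(abs(reference)) == 0) {
    stop("psnr: reference is identically zero", call. = FALSE)
  }
  mse <- mean((recon - reference)^2)
  if (mse == 0) return(200)
  min(10 * log10(max(reference)^2 / mse), 200)
}

# separable Gaussian filtering with edge-replicated padding
gauss_filter3 <- function(x, sigma, radius) {
  d <- dim(x)
  k <- exp(-0.5 * ((-radius):radius / sigma)^2)
  k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, radius), seq_len(n), rep(n, radius))
  xp <- x[pad_idx(d[1]), pad_idx(d[2]), pad_idx(d[3]), drop = FALSE]
  dp <- dim(xp)
  kern1 <- function(n) {
    v <- numeric(n)
    v[c(seq_len(radius + 1), n - seq_len(radius) + 1)] <-
      c(k[(radius + 1):(2 * radius + 1)], k[radius:1])
    v
  }
  K <- outer(outer(kern1(dp[1]), kern1(dp[2])), kern1(dp[3]))
  y <- Re(stats::fft(stats::fft(xp) * stats::fft(K), inverse = TRUE)) / length(xp)
  y[radius + seq_len(d[1]), radius + seq_len(d[2]), radius + seq_len(d[3]),
    drop = FALSE]
}

#' Structural similarity index (3D)
#'
#' Gaussian-window SSIM (`sigma = 1.5`, radius 5) computed over the full 3D
#' volume with `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, where `L` is the
#' reference dynamic range (or a fixed `L` supplied by the caller); the SSIM
#' map is averaged over all voxels.
#'
#' @param recon,reference Real arrays of identical shape.
#' @param L Dynamic range; default `max(reference) - min(reference)`.
#' @param sigma,radius Gaussian window parameters.
#' @return SSIM value in `[-1, 1]`; 1 iff the volumes are identical.
#' @export
ssim <- function(recon, reference, L = NULL, sigma = 1.5, radius = 5L) {
  if (!all(dim(recon) == dim(reference))) {
    stop("ssim: shape mismatch", call. = FALSE)
  }
  if (is.null(L)) L <- max(reference) - min(reference)
  if (L <= 0) L <- 1
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  mu1 <- gauss_filter3(recon, sigma, radius)
  mu2 <- gauss_filter3(reference, sigma, radius)
  s11 <- gauss_filter3(recon^2, sigma, radius) - mu1^2
  s22 <- gauss_filter3(reference^2, sigma, radius) - mu2^2
  s12 <- gauss_filter3(recon * reference, sigma, radius) - mu1 * mu2
  num <- (2 * mu1 * mu2 + c1) * (2 * s12 + c2)
  den <- (mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)
  mean(num / den)
}

#' Maximum intensity projections of a volume
#'
#' Per-axis maximum projections, each normalised to its own scale, written as
#' PNG images (one per axis) when `path_prefix` is given.
#'
#' @param vol Real 3D array.
#' @param path_prefix Optional file prefix; writes
#'   `<prefix>_mip_[xy|xz|yz].png`.
#' @return Invisibly, a list of the three projection matrices.
#' @export
write_mips <- function(vol, path_prefix = NULL) {
  mips <- list(
    xy = apply(vol, c(1, 2), max),
    xz = apply(vol, c(1, 3), max),
    yz = apply(vol, c(2, 3), max)
  )
  if (!is.null(path_prefix)) {
    for (nm in names(mips)) {
      m <- mips[[nm]]
      rng <- range(m)
      img <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
      png::writePNG(t(img)[rev(seq_len(ncol(img))), , drop = FALSE],
                    paste0(path_prefix, "_mip_", nm, ".png"))
    }
  }
  invisible(mips)
}

#' Method comparison over a test set
#'
#' Reconstructs every test sample with each requested method and tabulates
#' PSNR and SSIM (mean and standard deviation over the test set); optionally
#' writes maximum-intensity projections of the first test sample per method.
#'
#' @param dataset Output of [simulate_dataset()] (its `test` part is used).
#' @param methods Character vector from `c("tr", "fft", "pp", "mc_pp")`.
#' @param config A [run_config()].
#' @param grid A [make_grid()] grid.
#' @param states Named list of `pat_train_state` objects for the learned
#'   methods (names `"pp"`, `"mc_pp"`).
#' @param mip_dir Optional directory for MIP images.
#' @return A tibble with columns `method`, `mean_psnr`, `sd_psnr`,
#'   `mean_ssim`, `sd_ssim`, `n`.
#' @export
run_method_comparison <- function(dataset, methods = c("tr", "fft"),
                                  config, grid, states = list(),
                                  mip_dir = NULL) {
  rows <- lapply(methods, function(m) {
    state <- if (m %in% names(states)) {
      states[[m]]
    } else if (m %in% c("pp", "mc_pp")) {
      stop("missing trained state for method ", m, call. = FALSE)
    } else {
      list(method = m)
    }
    state$method <- m
    tab <- evaluate_operator(state, dataset$test, grid, config)
    if (!is.null(mip_dir) && length(dataset$test)) {
      rec <- pmax(
        reconstruct_volume(dataset$test[[1]]$g, m, config, grid, state), 0
      )
      write_mips(rec, file.path(mip_dir, m))
    }
    tibble::tibble(
      method = m,
      mean_psnr = attr(tab, "mean_psnr"), sd_psnr = attr(tab, "sd_psnr"),
      mean_ssim = attr(tab, "mean_ssim"), sd_ssim = attr(tab, "sd_ssim"),
      n = nrow(tab)
    )
  })
  do.call(rbind, rows)
}

#' PSNR as a function of the true test sound speed
#'
#' For each test sound speed, simulates a fresh test set at that (homogeneous)
#' speed, reconstructs with the configured `c_recon`, and returns the mean
#' PSNR -- the sweep used to study how reconstruction quality degrades when
#' the assumed speed is wrong, and how learned models depend on the training
#' range.
#'
#' @param method `"fft"`, `"tr"`, `"pp"` or `"mc_pp"`.
#' @param c_test_values Numeric vector of true sound speeds (m/s).
#' @param config A [run_config()] (its `n_test` phantoms are used per point).
#' @param grid A [make_grid()] grid.
#' @param state Trained state for learned methods.
#' @return A tibble with columns `c_test`, `mean_psnr`, `sd_psnr`.
#' @export
sos_sweep <- function(method, c_test_values, config, grid, state = NULL) {
  rows <- lapply(c_test_values, function(cc) {
    cfg <- config
    cfg$train_sos_spec <- cc
    cfg$test_sos_spec <- cc
    ds <- make_dataset(cfg, grid)
    ds <- simulate_dataset(list(train = list(), test = ds$test), grid, cfg)
    st <- if (is.null(state)) list(method = method) else state
    st$method <- method
    tab <- evaluate_operator(st, ds$test, grid, config)
    tibble::tibble(c_test = cc, mean_psnr = attr(tab, "mean_psnr"),
                   sd_psnr = attr(tab, "sd_psnr"))
  })
  do.call(rbind, rows)
}
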