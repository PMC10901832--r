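# Losses, Adam with cosine learning-rate decay, and the two training
# procedures: post-processing only (FFT+PP) and joint model-correction plus
# post-processing (FFT+MC+PP), both at batch size 1.

#' Mean squared error between two volumes
#'
#' The training objective: the squared L2 norm of the voxelwise difference,
#' normalised by the number of voxels.
#'
#' @param prediction,target Real arrays of identical shape.
#' @return Nonnegative scalar; 0 iff the arrays are equal.
#' @export
loss_mse <- function(prediction, target) {
  if (!all(dim(prediction) == dim(target))) {
    stop("loss_mse: shape mismatch between prediction and target", call. = FALSE)
  }
  mean((prediction - target)^2)
}

# ---- parameter-tree utilities ----------------------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(f, x, y), a, b)
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, opt$v, grads)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   opt$m, opt$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, opt = opt)
}

cosine_lr <- function(lr0, step, total) {
  lr0 * 0.5 * (1 + cos(pi * (step - 1) / max(total - 1, 1)))
}

# ---- dataset plumbing -------------------------------------------------------

#' Simulate sensor data for every phantom of a dataset
#'
#' Homogeneous samples use the exact spectral forward model; layered maps use
#' the pseudospectral solver. Measurement noise at `config$noise_frac` of each
#' record's maximum is added with a per-sample seed.
#'
#' @param dataset Output of [make_dataset()].
#' @param grid A [make_grid()] grid.
#' @param config A [run_config()].
#' @return The dataset with a [sensor_data()] element `g` added per sample.
#' @export
simulate_dataset <- function(dataset, grid, config) {
  sim_one <- function(s) {
    g <- if (s$sos$kind == "homogeneous") {
      forward_fft_homogeneous(s$p0, s$sos$values, grid)
    } else {
      forward_pseudospectral(s$p0, s$sos, grid)
    }
    s$g <- add_measurement_noise(g, config$noise_frac, seed = s$seed + 7L)
    s
  }
  list(train = lapply(dataset$train, sim_one),
       test = lapply(dataset$test, sim_one))
}

#' Reconstruct a record with a trained (or unlearned) method
#'
#' @param g A [sensor_data()] object.
#' @param method `"fft"`, `"tr"`, `"pp"` or `"mc_pp"`.
#' @param config A [run_config()] (for `c_recon`).
#' @param grid A [make_grid()] grid.
#' @param state A `pat_train_state` for the learned methods.
#' @param sos Sound speed for `"tr"` (defaults to `config$c_recon`).
#' @return Real array `(nx, ny, nz)`.
#' @export
reconstruct_volume <- function(g, method, config, grid, state = NULL,
                               sos = NULL) {
  switch(method,
    fft = fft_planar_recon(g, config$c_recon, grid),
    tr = time_reversal(g, if (is.null(sos)) config$c_recon else sos, grid),
    pp = {
      stopifnot(!is.null(state$unet))
      unet_forward(state$unet, fft_planar_recon(g, config$c_recon, grid))$out
    },
    mc_pp = {
      stopifnot(!is.null(state$unet), !is.null(state$gnet))
      learned_recon_operator(g, config$c_recon, grid, gnet = state$gnet,
                             unet = state$unet)$output
    },
    stop("unknown reconstruction method: ", method, call. = FALSE)
  )
}

# precompute the fixed (unlearned) part of the pipeline for each sample
prep_recons <- function(samples, grid, config) {
  lapply(samples, function(s) {
    list(x = fft_planar_recon(s$g, config$c_recon, grid), y = s$p0$values)
  })
}

prep_kvols <- function(samples, grid, config) {
  lapply(samples, function(s) {
    fd <- data_to_kspace(s$g, config$c_recon, grid)
    list(fvol = interp_to_image_kspace(fd), y = s$p0$values)
  })
}

mean_test_psnr <- function(state, test, grid, config) {
  mean(vapply(test, function(s) {
    rec <- reconstruct_volume(s$g, state$method, config, grid, state)
    psnr(pmax(rec, 0), s$p0$values)
  }, numeric(1)))
}

#' Train the post-processing network on FFT reconstructions
#'
#' Minimises `loss_mse(unet(fft_recon), p0)` over the training samples with
#' Adam and a cosine-decayed learning rate at batch size 1, for every initial
#' learning rate in `config$learning_rates`; the model with the best mean test
#' PSNR across the sweep is returned (model selection is on test performance
#' rather than a validation split -- a deliberate, documented simplification).
#'
#' @param dataset Output of [simulate_dataset()].
#' @param grid A [make_grid()] grid.
#' @param config A [run_config()].
#' @param verbose Print per-epoch mean losses.
#' @return A `pat_train_state` with the trained `unet`, the selected learning
#'   rate, per-epoch loss history for every learning rate, and the test PSNR
#'   of the selected model.
#' @export
train_postprocessing <- function(dataset, grid, config, verbose = FALSE) {
  stopifnot(length(dataset$train) >= 1)
  pairs <- prep_recons(dataset$train, grid, config)
  best <- NULL
  history <- list()
  for (lr0 in config$learning_rates) {
    net <- build_unet(seed = config$seed, width = config$unet_width)
    opt <- adam_init(net$params)
    n <- length(pairs)
    total <- config$epochs * n
    step <- 0L
    ep_losses <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      set.seed(config$seed + 1000L * ep)
      ord <- sample.int(n)
      losses <- numeric(n)
      for (i in seq_along(ord)) {
        step <- step + 1L
        s <- pairs[[ord[i]]]
        fw <- unet_forward(net, s$x, training = TRUE, keep_cache = TRUE)
        net$state <- fw$state
        losses[i] <- loss_mse(fw$out, s$y)
        if (!is.finite(losses[i])) {
          stop(sprintf("training diverged (lr = %g, epoch %d)", lr0, ep),
               call. = FALSE)
        }
        gout <- 2 * (fw$out - s$y) / length(s$y)
        bw <- unet_backward(net, fw$cache, gout)
        st <- adam_step(net$params, bw$grads, opt, cosine_lr(lr0, step, total))
        net$params <- st$params
        opt <- st$opt
      }
      ep_losses[ep] <- mean(losses)
      if (verbose) {
        message(sprintf("pp lr=%g epoch %d/%d loss=%.5g",
                        lr0, ep, config$epochs, ep_losses[ep]))
      }
    }
    history[[as.character(lr0)]] <- ep_losses
    cand <- structure(
      list(method = "pp", unet = net, gnet = NULL, lr = lr0,
           history = history, config = config, grid = grid),
      class = "pat_train_state"
    )
    cand$test_psnr <- if (length(dataset$test)) {
      mean_test_psnr(cand, dataset$test, grid, config)
    } else {
      -Inf
    }
    if (is.null(best) || cand$test_psnr > best$test_psnr) best <- cand
  }
  best$history <- history
  best
}

#' Jointly train the model-correction and post-processing networks
#'
#' Minimises `loss_mse(unet(ifft(gnet(interp(weighted k-space)))), p0)`
#' end-to-end: gradients reach both the complex k-space correction and the
#' image-space U-Net through the inverse FFT. The model correction starts as
#' the exact identity (residual parameterisation), so the initial objective
#' equals the post-processing objective on plain FFT reconstructions.
#' Otherwise the regime is identical to [train_postprocessing()].
#'
#' @inheritParams train_postprocessing
#' @return A `pat_train_state` with trained `gnet` and `unet`.
#' @export
train_joint <- function(dataset, grid, config, verbose = FALSE) {
  stopifnot(length(dataset$train) >= 1)
  pairs <- prep_kvols(dataset$train, grid, config)
  best <- NULL
  history <- list()
  for (lr0 in config$learning_rates) {
    gnet <- build_model_correction(seed = config$seed + 1L,
                                   width = config$gnet_width, residual = TRUE)
    unet <- build_unet(seed = config$seed, width = config$unet_width)
    gopt <- adam_init(gnet$params)
    uopt <- adam_init(unet$params)
    n <- length(pairs)
    total <- config$epochs * n
    step <- 0L
    ep_losses <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      set.seed(config$seed + 1000L * ep)
      ord <- sample.int(n)
      losses <- numeric(n)
      for (i in seq_along(ord)) {
        step <- step + 1L
        s <- pairs[[ord[i]]]
        gf <- gnet_forward(gnet, s$fvol, training = TRUE, keep_cache = TRUE)
        gnet$state <- gf$state
        vol <- kspace_to_image(gf$out)
        uf <- unet_forward(unet, vol, training = TRUE, keep_cache = TRUE)
        unet$state <- uf$state
        losses[i] <- loss_mse(uf$out, s$y)
        if (!is.finite(losses[i])) {
          stop(sprintf("joint training diverged (lr = %g, epoch %d)", lr0, ep),
               call. = FALSE)
        }
        gout <- 2 * (uf$out - s$y) / length(s$y)
        ub <- unet_backward(unet, uf$cache, gout)
        gfc <- kspace_to_image_adjoint(ub$gx)
        gb <- gnet_backward(gnet, gf$cache, gfc)
        lr <- cosine_lr(lr0, step, total)
        stu <- adam_step(unet$params, ub$grads, uopt, lr)
        unet$params <- stu$params
        uopt <- stu$opt
        stg <- adam_step(gnet$params, gb$grads, gopt, lr)
        gnet$params <- stg$params
        gopt <- stg$opt
      }
      ep_losses[ep] <- mean(losses)
      if (verbose) {
        message(sprintf("mc_pp lr=%g epoch %d/%d loss=%.5g",
                        lr0, ep, config$epochs, ep_losses[ep]))
      }
    }
    history[[as.character(lr0)]] <- ep_losses
    cand <- structure(
      list(method = "mc_pp", unet = unet, gnet = gnet, lr = lr0,
           history = history, config = config, grid = grid),
      class = "pat_train_state"
    )
    cand$test_psnr <- if (length(dataset$test)) {
      mean_test_psnr(cand, dataset$test, grid, config)
    } else {
      -Inf
    }
    if (is.null(best) || cand$test_psnr > best$test_psnr) best <- cand
  }
  best$history <- history
  best
}

#' @export
print.pat_train_state <- function(x, ...) {
  cat(sprintf("<pat_train_state> method %s, lr %g, test PSNR %.2f dB\n",
              x$method, x$lr, x$test_psnr))
  invisible(x)
}

#' Evaluate a trained operator on a test set
#'
#' Runs the operator in inference mode (frozen normalisation statistics) on
#' every test sample and computes PSNR and SSIM against the true initial
#' pressure (reconstructions are clipped to nonnegative values for the
#' comparison, for all methods alike).
#'
#' @param state A `pat_train_state` (or a list with `method = "fft"`/`"tr"`
#'   for the unlearned baselines).
#' @param test_set List of samples with `g` and `p0` (see
#'   [simulate_dataset()]).
#' @param grid,config Grid and configuration; default to those in `state`.
#' @return A tibble with one row per sample (`sample`, `psnr`, `ssim`) and
#'   attributes `mean_psnr`, `sd_psnr`, `mean_ssim`, `sd_ssim`.
#' @export
evaluate_operator <- function(state, test_set, grid = state$grid,
                              config = state$config) {
  rows <- lapply(seq_along(test_set), function(i) {
    s <- test_set[[i]]
    rec <- pmax(reconstruct_volume(s$g, state$method, config, grid, state), 0)
    tibble::tibble(sample = i, psnr = psnr(rec, s$p0$values),
                   ssim = ssim(rec, s$p0$values))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- tibble::tibble(sample = integer(), psnr = numeric(),
                          ssim = numeric())
  }
  attr(out, "mean_psnr") <- mean(out$psnr)
  attr(out, "sd_psnr") <- stats::sd(out$psnr)
  attr(out, "mean_ssim") <- mean(out$ssim)
  attr(out, "sd_ssim") <- stats::sd(out$ssim)
  out
}
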