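# Run configuration: scenario, reconstruction sound speed, dataset sizes,
# noise level, training schedule. All quantities are SI (m, s, m/s)
# internally; YAML config files may use mm and MHz with explicit conversion at
# the boundary (see read_run_config()).

#' Run configuration
#'
#' Bundles the experiment settings shared by dataset generation, training and
#' evaluation.
#'
#' @param scenario One of `"fixed_sos"`, `"variable_sos"`, `"skin"`,
#'   `"skull"`.
#' @param c_recon Scalar sound speed assumed by the reconstruction (m/s);
#'   1500 m/s, the usual soft-tissue value, by default.
#' @param train_sos_spec Fixed value or `c(lo, hi)` interval (m/s) from which
#'   each training sample's homogeneous sound speed is drawn. Ignored for the
#'   layered scenarios, whose per-layer intervals are fixed by the scenario.
#' @param test_sos_spec As `train_sos_spec`, for test samples; defaults to
#'   `train_sos_spec`.
#' @param n_train,n_test Dataset sizes.
#' @param noise_frac Measurement-noise standard deviation as a fraction of the
#'   clean data maximum (default 0.01, i.e. 1% of peak).
#' @param learning_rates Initial learning rates swept during training
#'   (full-scale default sweep: `1e-4`, `1e-3`, `1e-2`).
#' @param epochs Training epochs per learning rate.
#' @param seed Base integer seed for all randomness derived from this
#'   configuration.
#' @param unet_width Base channel width of the post-processing U-Net
#'   (doubled at each of its three downsamplings; 32 at full scale).
#' @param gnet_width Channel width of the model-correction network (32 at
#'   full scale).
#' @param phantom List of vessel-phantom generator parameters
#'   (`n_branches`, `radius_range_vox`, `smoothing_sigma_vox`).
#' @return A `pat_run_config` object.
#' @export
run_config <- function(scenario = c("variable_sos", "fixed_sos", "skin", "skull"),
                       c_recon = 1500,
                       train_sos_spec = c(1400, 1600),
                       test_sos_spec = train_sos_spec,
                       n_train = 20, n_test = 5,
                       noise_frac = 0.01,
                       learning_rates = 1e-2,
                       epochs = 8,
                       seed = 1,
                       unet_width = 8,
                       gnet_width = 8,
                       phantom = list(n_branches = 6,
                                      radius_range_vox = c(1, 3),
                                      smoothing_sigma_vox = 1)) {
  scenario <- match.arg(scenario)
  if (c_recon <= 0) stop("c_recon must be positive", call. = FALSE)
  for (spec in list(train_sos_spec, test_sos_spec)) {
    if (!length(spec) %in% c(1L, 2L) || any(spec <= 0) ||
        (length(spec) == 2L && spec[1] > spec[2])) {
      stop("sound-speed specifications must be a positive value or c(lo, hi) with lo <= hi",
           call. = FALSE)
    }
  }
  if (noise_frac < 0) stop("noise_frac must be >= 0", call. = FALSE)
  if (n_train < 0 || n_test < 0) stop("dataset sizes must be >= 0", call. = FALSE)
  if (any(learning_rates <= 0) || epochs < 1) {
    stop("learning rates must be positive and epochs >= 1", call. = FALSE)
  }
  structure(
    list(scenario = scenario, c_recon = c_recon,
         train_sos_spec = train_sos_spec, test_sos_spec = test_sos_spec,
         n_train = as.integer(n_train), n_test = as.integer(n_test),
         noise_frac = noise_frac, learning_rates = learning_rates,
         epochs = as.integer(epochs), seed = as.integer(seed),
         unet_width = as.integer(unet_width),
         gnet_width = as.integer(gnet_width),
         phantom = phantom),
    class = "pat_run_config"
  )
}

#' @export
print.pat_run_config <- function(x, ...) {
  spec <- paste(format(x$train_sos_spec), collapse = "-")
  cat(sprintf("<pat_run_config> scenario %s, train SoS %s m/s, recon %g m/s, %d train / %d test, seed %d\n",
              x$scenario, spec, x$c_recon, x$n_train, x$n_test, x$seed))
  invisible(x)
}

#' Write a run configuration (and grid) to a YAML file
#'
#' Every run records its resolved configuration and seed so it can be
#' re-executed identically.
#'
#' @param config A [run_config()].
#' @param grid A [make_grid()] grid.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, grid, path) {
  stopifnot(inherits(config, "pat_run_config"))
  assert_grid(grid)
  obj <- unclass(config)
  obj$grid <- unclass(grid)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a run configuration (and grid) from a YAML file
#'
#' Lengths in the file are metres and times seconds, matching
#' [write_run_config()]; the optional keys `dx_mm` and `sampling_mhz` may be
#' used instead of `dx`/`dt` for mm / MHz convenience and are converted on
#' read.
#'
#' @param path YAML file written by [write_run_config()] (or by hand).
#' @return List with elements `config` (a [run_config()]) and `grid`.
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  g <- obj$grid
  if (!is.null(g$dx_mm)) g$dx <- g$dx_mm * 1e-3
  if (!is.null(g$sampling_mhz)) g$dt <- 1 / (g$sampling_mhz * 1e6)
  grid <- make_grid(g$nx, g$ny, g$nz, g$dx, g$nt, g$dt)
  keep <- intersect(names(obj), names(formals(run_config)))
  cfg_args <- obj[keep]
  if (!is.null(cfg_args$train_sos_spec)) {
    cfg_args$train_sos_spec <- as.numeric(unlist(cfg_args$train_sos_spec))
  }
  if (!is.null(cfg_args$test_sos_spec)) {
    cfg_args$test_sos_spec <- as.numeric(unlist(cfg_args$test_sos_spec))
  }
  if (!is.null(cfg_args$phantom)) {
    cfg_args$phantom$radius_range_vox <-
      as.numeric(unlist(cfg_args$phantom$radius_range_vox))
  }
  config <- do.call(run_config, cfg_args)
  list(config = config, grid = grid)
}
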