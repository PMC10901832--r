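# Synthetic initial-pressure volumes and sound-speed maps: procedural
# vessel-mimicking phantoms (biased random-walk centerlines with Poisson
# bifurcations, voxelised by radius and Gaussian-smoothed) and homogeneous /
# layered (skin, skull) sound-speed scenarios.

#' Initial pressure container
#'
#' @param values Nonnegative, finite real `(nx, ny, nz)` array; by generator
#'   contract the maximum is 1 for non-empty volumes.
#' @param grid A [make_grid()] grid.
#' @return A `pat_p0` object.
#' @export
initial_pressure <- function(values, grid) {
  assert_grid(grid)
  stopifnot(is.numeric(values), all(dim(values) == c(grid$nx, grid$ny, grid$nz)))
  if (!all(is.finite(values)) || any(values < 0)) {
    stop("initial pressure must be finite and nonnegative", call. = FALSE)
  }
  structure(list(values = values, grid = grid), class = "pat_p0")
}

#' Sound-speed map container
#'
#' @param values Positive scalar (homogeneous) or real `(nx, ny, nz)` array
#'   (m/s).
#' @param grid A [make_grid()] grid.
#' @param kind `"homogeneous"` or `"layered"`.
#' @param layers Optional list of per-layer voxel slab index ranges.
#' @return A `pat_sos` object.
#' @export
sos_map <- function(values, grid, kind = if (length(values) == 1L) "homogeneous" else "layered",
                    layers = NULL) {
  assert_grid(grid)
  if (any(values <= 0) || !all(is.finite(values))) {
    stop("sound speed values must be positive and finite", call. = FALSE)
  }
  if (length(values) != 1L) {
    stopifnot(all(dim(values) == c(grid$nx, grid$ny, grid$nz)))
  }
  structure(list(values = values, grid = grid, kind = kind, layers = layers),
            class = "pat_sos")
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter implemented by FFT (circular boundaries; phantom
#' generators keep structures away from the faces so wrap-around is
#' negligible).
#'
#' @param x Real 3D array.
#' @param sigma_vox Standard deviation in voxels; 0 returns `x` unchanged.
#' @return Smoothed array of the same shape.
#' @export
smooth_volume <- function(x, sigma_vox) {
  if (sigma_vox <= 0) return(x)
  d <- dim(x)
  kern1 <- function(n) {
    i <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-0.5 * (i / sigma_vox)^2)
    k / sum(k)
  }
  K <- outer(outer(kern1(d[1]), kern1(d[2])), kern1(d[3]))
  Re(stats::fft(stats::fft(x) * stats::fft(K), inverse = TRUE)) / length(x)
}

#' Procedural vessel-mimicking phantom
#'
#' Emulates smoothed tubular vessel trees: biased 3D random-walk centerlines
#' (direction persistence), occasional Poisson bifurcations, hard-sphere
#' voxelisation with a per-branch radius, Gaussian smoothing and
#' max-normalisation to 1. Fully reproducible from `seed`.
#'
#' @param grid A [make_grid()] grid.
#' @param seed Integer seed.
#' @param n_branches Number of seeded root branches; 0 gives an all-zero
#'   volume with a warning.
#' @param radius_range_vox Length-2 range of branch radii in voxels.
#' @param smoothing_sigma_vox Gaussian smoothing width in voxels.
#' @param persistence Direction persistence of the random walk in `[0, 1)`.
#' @param bifurcation_rate Expected bifurcations per centerline step.
#' @param margin_frac Fraction of each axis kept clear of structures.
#' @param smooth Apply the Gaussian smoothing and normalisation (set `FALSE`
#'   to obtain the raw binary tubes, e.g. to zero-fill regions before
#'   smoothing).
#' @return A [initial_pressure()] object (values in `[0, 1]`).
#' @export
generate_vessel_phantom <- function(grid, seed, n_branches = 8,
                                    radius_range_vox = c(1, 3),
                                    smoothing_sigma_vox = 1,
                                    persistence = 0.85,
                                    bifurcation_rate = 0.03,
                                    margin_frac = 0.12,
                                    smooth = TRUE) {
  assert_grid(grid)
  if (n_branches < 0 || any(radius_range_vox <= 0) ||
      radius_range_vox[1] > radius_range_vox[2] || smoothing_sigma_vox < 0) {
    stop("invalid vessel phantom parameters", call. = FALSE)
  }
  dims <- c(grid$nx, grid$ny, grid$nz)
  vol <- array(0, dims)
  if (n_branches == 0) {
    warning("n_branches = 0: returning an all-zero volume")
    return(initial_pressure(vol, grid))
  }
  set.seed(seed)
  lo <- pmax(ceiling(dims * margin_frac), 2)
  hi <- pmin(floor(dims * (1 - margin_frac)), dims - 1)
  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  # precompute sphere offsets per integer radius
  max_r <- ceiling(radius_range_vox[2])
  ball_offsets <- lapply(seq_len(max_r), function(r) {
    s <- -r:r
    off <- as.matrix(expand.grid(s, s, s))
    off[rowSums(off^2) <= r^2 + 1e-9, , drop = FALSE]
  })
  stamp <- function(pos, r) {
    off <- ball_offsets[[max(1L, min(max_r, round(r)))]]
    pts <- sweep(off, 2, round(pos), "+")
    keep <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
      pts[, 2] >= 1 & pts[, 2] <= dims[2] &
      pts[, 3] >= 1 & pts[, 3] <= dims[3]
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts)) vol[pts] <<- 1
  }
  queue <- lapply(seq_len(n_branches), function(i) {
    list(
      pos = lo + stats::runif(3) * (hi - lo),
      dir = rand_dir(),
      radius = stats::runif(1, radius_range_vox[1], radius_range_vox[2]),
      steps = round(0.6 * max(dims) + stats::runif(1) * 0.6 * max(dims))
    )
  })
  total <- n_branches
  max_total <- 4L * n_branches
  step_len <- 0.6
  while (length(queue)) {
    br <- queue[[1]]
    queue <- queue[-1]
    pos <- br$pos
    dir <- br$dir
    for (s in seq_len(br$steps)) {
      stamp(pos, br$radius)
      dir <- persistence * dir + (1 - persistence) * rand_dir()
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + step_len * dir
      if (any(pos < lo) || any(pos > hi)) break
      if (total < max_total && stats::runif(1) < bifurcation_rate) {
        total <- total + 1L
        queue[[length(queue) + 1L]] <- list(
          pos = pos,
          dir = (dir + rand_dir()) / 2,
          radius = max(radius_range_vox[1], br$radius * stats::runif(1, 0.6, 0.9)),
          steps = max(4L, round(br$steps / 2))
        )
      }
    }
  }
  if (smooth) {
    vol <- smooth_volume(vol, smoothing_sigma_vox)
    vol <- pmax(vol, 0)
    if (max(vol) > 0) vol <- vol / max(vol)
  }
  initial_pressure(vol, grid)
}

#' Draw a homogeneous speed of sound
#'
#' A fixed specification (single value) is returned as-is; an interval
#' specification `c(lo, hi)` yields a uniform draw.
#'
#' @param spec Single value (fixed) or length-2 numeric interval (m/s).
#' @param seed Optional integer seed.
#' @return Scalar sound speed (m/s).
#' @export
sample_homogeneous_sos <- function(spec, seed = NULL) {
  if (!is.numeric(spec) || !length(spec) %in% c(1L, 2L) || any(spec <= 0)) {
    stop("spec must be a positive value or interval", call. = FALSE)
  }
  if (length(spec) == 2L && spec[1] > spec[2]) {
    stop("invalid interval: lower bound exceeds upper bound", call. = FALSE)
  }
  if (length(spec) == 1L || spec[1] == spec[2]) return(spec[1])
  if (!is.null(seed)) set.seed(seed)
  stats::runif(1, spec[1], spec[2])
}

#' Layered sound-speed specification
#'
#' Ordered layers below the sensor plane with per-layer uniform sound-speed
#' intervals, a remainder interval for the rest of the depth and a masking
#' rule for the initial pressure.
#'
#' @param thickness_m Numeric vector of layer thicknesses (m).
#' @param sos_intervals List of `c(lo, hi)` intervals (m/s), one per layer.
#' @param remainder_interval `c(lo, hi)` for the remaining depth.
#' @param exclusion_rule One of `"none"`, `"exclude_first_layer"` (zero the
#'   initial pressure on the first layer; skin scenario) or
#'   `"restrict_to_remainder"` (keep initial pressure only below the layers;
#'   skull scenario).
#' @return A `pat_layer_spec` object.
#' @export
layer_spec <- function(thickness_m, sos_intervals, remainder_interval,
                       exclusion_rule = c("none", "exclude_first_layer",
                                          "restrict_to_remainder")) {
  exclusion_rule <- match.arg(exclusion_rule)
  stopifnot(length(thickness_m) == length(sos_intervals))
  if (any(thickness_m <= 0)) stop("layer thicknesses must be positive", call. = FALSE)
  for (iv in c(sos_intervals, list(remainder_interval))) {
    if (length(iv) != 2L || iv[1] > iv[2] || any(iv <= 0)) {
      stop("each sound-speed interval must be c(lo, hi) with 0 < lo <= hi",
           call. = FALSE)
    }
  }
  structure(
    list(thickness_m = thickness_m, sos_intervals = sos_intervals,
         remainder_interval = remainder_interval,
         exclusion_rule = exclusion_rule),
    class = "pat_layer_spec"
  )
}

#' Skin scenario layer specification
#'
#' Epidermis 0.212 mm in `[1635, 1655]` m/s, dermis 2.12 mm in
#' `[1585, 1605]` m/s, hypodermis 1.696 mm in `[1440, 1460]` m/s, remaining
#' depth soft tissue in `[1480, 1520]` m/s; the initial pressure is excluded
#' from the epidermis.
#'
#' @return A [layer_spec()].
#' @export
skin_layer_spec <- function() {
  layer_spec(
    thickness_m = c(0.212e-3, 2.12e-3, 1.696e-3),
    sos_intervals = list(c(1635, 1655), c(1585, 1605), c(1440, 1460)),
    remainder_interval = c(1480, 1520),
    exclusion_rule = "exclude_first_layer"
  )
}

#' Skull scenario layer specification
#'
#' Skin 0.212 mm in `[1580, 1620]` m/s, skull 0.428 mm in `[2780, 2820]` m/s,
#' remaining depth brain in `[1520, 1560]` m/s; the initial pressure is
#' restricted to the brain region.
#'
#' @return A [layer_spec()].
#' @export
skull_layer_spec <- function() {
  layer_spec(
    thickness_m = c(0.212e-3, 0.428e-3),
    sos_intervals = list(c(1580, 1620), c(2780, 2820)),
    remainder_interval = c(1520, 1560),
    exclusion_rule = "restrict_to_remainder"
  )
}

#' Voxel slab counts of a layered specification on a grid
#'
#' Layer `l` occupies `round(thickness_l / dx)` voxel slabs from the sensor
#' plane downward; the built-in scenario thicknesses are exact multiples of
#' the full-scale spacing, so the rounding is lossless there.
#'
#' @param spec A [layer_spec()].
#' @param grid A [make_grid()] grid.
#' @return Integer vector of slab counts (one per layer).
#' @export
layer_slab_counts <- function(spec, grid) {
  stopifnot(inherits(spec, "pat_layer_spec"))
  assert_grid(grid)
  counts <- as.integer(round(spec$thickness_m / grid$dx))
  if (any(counts == 0)) {
    stop("a layer thickness rounds to zero voxel slabs on this grid", call. = FALSE)
  }
  if (sum(counts) > grid$nz) {
    stop("layer thicknesses exceed the domain depth", call. = FALSE)
  }
  counts
}

layer_slab_ranges <- function(spec, grid) {
  counts <- layer_slab_counts(spec, grid)
  ends <- cumsum(counts)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  ranges <- Map(seq, starts, ends)
  remainder <- if (ends[length(ends)] < grid$nz) {
    seq(ends[length(ends)] + 1L, grid$nz)
  } else {
    integer(0)
  }
  list(layers = ranges, remainder = remainder)
}

#' Build a layered sound-speed map
#'
#' Every voxel of layer `l` is drawn i.i.d. uniform from that layer's
#' interval; the remaining depth is filled from the remainder interval.
#'
#' @param grid A [make_grid()] grid.
#' @param spec A [layer_spec()].
#' @param seed Optional integer seed.
#' @return A [sos_map()] of kind `"layered"` with per-layer slab indices.
#' @export
build_layered_sos <- function(grid, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sl <- layer_slab_ranges(spec, grid)
  values <- array(0, c(grid$nx, grid$ny, grid$nz))
  nxy <- grid$nx * grid$ny
  for (l in seq_along(sl$layers)) {
    iv <- spec$sos_intervals[[l]]
    nvox <- nxy * length(sl$layers[[l]])
    values[, , sl$layers[[l]]] <- stats::runif(nvox, iv[1], iv[2])
  }
  if (length(sl$remainder)) {
    iv <- spec$remainder_interval
    values[, , sl$remainder] <- stats::runif(nxy * length(sl$remainder), iv[1], iv[2])
  }
  sos_map(values, grid, kind = "layered",
          layers = c(sl$layers, list(remainder = sl$remainder)))
}

#' Apply a layer-scenario region mask to an initial pressure
#'
#' Skin rule (`exclude_first_layer`): zero the first layer, re-smooth (the
#' zero-fill happens before the smoothing so that smoothing cannot leak mass
#' back into the excluded layer, which is re-zeroed after the filter) and
#' renormalise. Skull rule (`restrict_to_remainder`): keep the initial
#' pressure only on the remainder (brain) region. `none` is the identity.
#'
#' @param p0 An [initial_pressure()] object or `(nx, ny, nz)` array.
#' @param spec A [layer_spec()].
#' @param grid A [make_grid()] grid.
#' @param smoothing_sigma_vox Smoothing width used in the re-smoothing step of
#'   the skin rule (0 to skip).
#' @return An [initial_pressure()] object.
#' @export
apply_region_mask <- function(p0, spec, grid, smoothing_sigma_vox = 1) {
  if (inherits(p0, "pat_p0")) p0 <- p0$values
  assert_grid(grid)
  stopifnot(inherits(spec, "pat_layer_spec"),
            all(dim(p0) == c(grid$nx, grid$ny, grid$nz)))
  if (spec$exclusion_rule == "none") return(initial_pressure(p0, grid))
  sl <- layer_slab_ranges(spec, grid)
  zap <- switch(spec$exclusion_rule,
    exclude_first_layer = sl$layers[[1]],
    restrict_to_remainder = setdiff(seq_len(grid$nz), sl$remainder)
  )
  p0[, , zap] <- 0
  if (spec$exclusion_rule == "exclude_first_layer" && smoothing_sigma_vox > 0 &&
      max(p0) > 0) {
    p0 <- smooth_volume(p0, smoothing_sigma_vox)
    p0 <- pmax(p0, 0)
    p0[, , zap] <- 0
  }
  if (max(p0) > 0) p0 <- p0 / max(p0)
  initial_pressure(p0, grid)
}

#' Generate a phantom/sound-speed dataset
#'
#' Yields `n_train + n_test` seeded `(p0, sos)` pairs according to the
#' configured scenario; each sample uses its own deterministic seed derived
#' from the configuration seed, with train and test streams disjoint.
#'
#' Train pairs draw their sound speed from `config$train_sos_spec`, test pairs
#' from `config$test_sos_spec` (which defaults to the training specification;
#' the evaluation harness sets it to the full uncertainty interval).
#'
#' @param config A [run_config()].
#' @param grid A [make_grid()] grid.
#' @return List with elements `train` and `test`, each a list of samples
#'   `list(p0, sos, seed)`.
#' @export
make_dataset <- function(config, grid) {
  stopifnot(inherits(config, "pat_run_config"))
  assert_grid(grid)
  gen_one <- function(s, sos_spec) {
    spec <- scenario_layer_spec(config$scenario)
    if (is.null(spec)) {
      p0 <- generate_vessel_phantom(
        grid, seed = s,
        n_branches = config$phantom$n_branches,
        radius_range_vox = config$phantom$radius_range_vox,
        smoothing_sigma_vox = config$phantom$smoothing_sigma_vox
      )
      sos <- sos_map(sample_homogeneous_sos(sos_spec, seed = s + 1L),
                     grid, kind = "homogeneous")
    } else {
      raw <- generate_vessel_phantom(
        grid, seed = s,
        n_branches = config$phantom$n_branches,
        radius_range_vox = config$phantom$radius_range_vox,
        smoothing_sigma_vox = config$phantom$smoothing_sigma_vox,
        smooth = FALSE
      )
      v <- raw$values
      sl <- layer_slab_ranges(spec, grid)
      zap <- switch(spec$exclusion_rule,
        exclude_first_layer = sl$layers[[1]],
        restrict_to_remainder = setdiff(seq_len(grid$nz), sl$remainder),
        none = integer(0)
      )
      v[, , zap] <- 0
      v <- smooth_volume(v, config$phantom$smoothing_sigma_vox)
      v <- pmax(v, 0)
      v[, , zap] <- 0
      if (max(v) > 0) v <- v / max(v)
      p0 <- initial_pressure(v, grid)
      sos <- build_layered_sos(grid, spec, seed = s + 1L)
    }
    list(p0 = p0, sos = sos, seed = s)
  }
  train_seeds <- config$seed + 100L * seq_len(config$n_train)
  test_seeds <- config$seed + 100L * config$n_train + 100L * seq_len(config$n_test) + 50L
  list(
    train = lapply(train_seeds, gen_one, sos_spec = config$train_sos_spec),
    test = lapply(test_seeds, gen_one, sos_spec = config$test_sos_spec)
  )
}

# test-set sound speeds always span the full uncertainty range in the
# homogeneous scenarios; layered scenarios redraw layer values per sample
scenario_layer_spec <- function(scenario) {
  switch(scenario,
    skin = skin_layer_spec(),
    skull = skull_layer_spec(),
    NULL
  )
}
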