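#' Configuration for the synthetic resting-state generator
#'
#' Collects every knob of the SimTB-style simulator. The defaults reproduce
#' the reference protocol: 5 subjects, 150 time points at TR = 2 s on a
#' 100 x 100 slice, 6 spatial components, four event types (standard, target,
#' novel, spike) occurring independently each TR with probabilities
#' .06/.075/.075/.05, HRF-convolved component time courses, a smooth positive
#' baseline, and Rician noise at a per-subject contrast-to-noise ratio drawn
#' uniformly from 0.2-0.65.
#'
#' @param n_subjects Number of subjects (default 5).
#' @param n_time Time points per subject (default 150).
#' @param tr Repetition time in seconds (default 2).
#' @param grid `c(height, width)` of the 2D slice (default `c(100, 100)`).
#' @param n_components Number of spatial components (default 6).
#' @param event_probs Per-TR probability of each of the four event types
#'   (default `c(.06, .075, .075, .05)`).
#' @param event_amps Amplitude per event type (default `c(1, 1.2, 1.2, 1.5)`,
#'   a documented stand-in; only relative scale matters).
#' @param cnr_range Contrast-to-noise range `c(low, high)`, low > 0; each
#'   subject's CNR (peak noise-free signal deviation over noise sigma) is
#'   drawn uniformly from it (default `c(0.2, 0.65)`).
#' @param blob_sigma Spatial spread of the isotropic Gaussian components in
#'   voxels (default 6% of the smaller grid dimension).
#' @param spatial_jitter Per-subject variability of the component layout:
#'   list with `translate` (max |shift| in voxels), `rotate` (max |rotation|
#'   of the component constellation, degrees) and `spread` (max relative
#'   change of `blob_sigma`). Defaults 3 voxels / 5 degrees / 0.15.
#' @param rng_seed Master seed; all randomness (event trains, jitter, CNR,
#'   noise) flows from it through fixed per-subject substreams.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 5L, n_time = 150L, tr = 2,
                       grid = c(100L, 100L), n_components = 6L,
                       event_probs = c(0.06, 0.075, 0.075, 0.05),
                       event_amps = c(1, 1.2, 1.2, 1.5),
                       cnr_range = c(0.2, 0.65),
                       blob_sigma = NULL,
                       spatial_jitter = list(translate = 3, rotate = 5,
                                             spread = 0.15),
                       rng_seed = 1L) {
  check_scalar(n_subjects, "n_subjects", lower = 1, integerish = TRUE)
  check_scalar(n_time, "n_time", lower = 2, integerish = TRUE)
  check_scalar(tr, "tr", lower = 0, strict_lower = TRUE)
  if (length(grid) != 2 || any(grid < 2) || any(grid != round(grid))) {
    abort("`grid` must be two integers >= 2.")
  }
  check_scalar(n_components, "n_components", lower = 1, integerish = TRUE)
  if (!is.numeric(event_probs) || any(event_probs < 0) || any(event_probs > 1)) {
    abort("`event_probs` must be probabilities in [0, 1].")
  }
  if (length(event_amps) != length(event_probs) || any(event_amps <= 0)) {
    abort("`event_amps` must be positive, one per event type.")
  }
  if (length(cnr_range) != 2 || cnr_range[1] <= 0 ||
      cnr_range[1] > cnr_range[2]) {
    abort("`cnr_range` must be c(low, high) with 0 < low <= high.")
  }
  blob_sigma <- blob_sigma %||% (0.06 * min(grid))
  check_scalar(blob_sigma, "blob_sigma", lower = 0, strict_lower = TRUE)
  kern_len <- length(hrf_kernel(tr))
  if (n_time < 2 * kern_len) {
    abort(sprintf("`n_time` must be at least twice the HRF length (%d samples).",
                  kern_len))
  }
  check_scalar(rng_seed, "rng_seed", integerish = TRUE)
  structure(list(
    n_subjects = as.integer(n_subjects), n_time = as.integer(n_time),
    tr = tr, grid = as.integer(grid), n_components = as.integer(n_components),
    event_probs = event_probs, event_amps = event_amps,
    cnr_range = cnr_range, blob_sigma = blob_sigma,
    spatial_jitter = spatial_jitter, rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

# Event types assigned to one component: "standard" plus one of the others,
# round-robin over components.
component_types <- function(component, n_types) {
  if (n_types == 1L) return(1L)
  sort(unique(c(1L, 2L + (component - 1L) %% (n_types - 1L))))
}

#' Simulate one component's event train
#'
#' Each TR independently carries an event of type k with probability
#' `event_probs[k]`, for the event types assigned to the component
#' ("standard" plus one other, round-robin). The binary train is the union
#' across those types; when types coincide the larger amplitude wins.
#'
#' @param config A [sim_config()].
#' @param component Component index (1-based).
#' @param seed Seed for this train (default derived from the config seed).
#' @return List with `train` (binary 0/1, length `n_time`), `amplitude`
#'   (numeric, 0 off-event) and `types` (event-type indices used).
#' @export
sim_event_train <- function(config, component,
                            seed = child_seed(config$rng_seed, component)) {
  stopifnot(inherits(config, "sim_config"))
  check_scalar(component, "component", lower = 1, upper = config$n_components,
               integerish = TRUE)
  types <- component_types(as.integer(component), length(config$event_probs))
  withr::with_seed(seed, {
    amp <- rep(0, config$n_time)
    for (k in types) {
      hit <- rbinom(config$n_time, 1L, config$event_probs[k]) == 1L
      amp[hit] <- pmax(amp[hit], config$event_amps[k])
    }
    list(train = as.integer(amp > 0), amplitude = amp, types = types)
  })
}

# Isotropic 2D Gaussian blob on a grid; peak value 1.
gaussian_blob <- function(grid, center, sigma) {
  r <- outer((seq_len(grid[1]) - center[1])^2,
             (seq_len(grid[2]) - center[2])^2, `+`)
  exp(-r / (2 * sigma^2))
}

# Nominal component centers: near-regular layout over the slice interior.
component_centers <- function(grid, n_components) {
  ncol_ <- ceiling(sqrt(n_components))
  nrow_ <- ceiling(n_components / ncol_)
  xs <- grid[2] * seq(0.22, 0.78, length.out = ncol_)
  ys <- grid[1] * seq(0.25, 0.75, length.out = nrow_)
  centers <- expand.grid(y = ys, x = xs)[seq_len(n_components), ]
  as.matrix(centers[, c("y", "x")])
}

# Rician corruption: magnitude of the signal plus complex Gaussian noise.
rician <- function(signal, sigma, seed) {
  withr::with_seed(seed, {
    n1 <- array(rnorm(length(signal), 0, sigma), dim = dim(signal) %||%
                  length(signal))
    n2 <- array(rnorm(length(signal), 0, sigma), dim = dim(signal) %||%
                  length(signal))
    out <- sqrt((signal + n1)^2 + n2^2)
    if (!is.null(dim(signal))) dim(out) <- dim(signal)
    out
  })
}

# Smooth positive baseline field, deterministic given the grid.
baseline_field <- function(grid) {
  c0 <- (grid + 1) / 2
  100 + 20 * gaussian_blob(grid, c0, 0.5 * min(grid))
}

#' Simulate a SimTB-style synthetic resting-state dataset
#'
#' For each subject: the nominal component constellation is jittered
#' (translated, rotated about the slice centre, and its spread rescaled,
#' all within `spatial_jitter`); each component receives an HRF-convolved
#' event train; voxel time courses are the linear combination of the spatial
#' maps weighted by the component time courses plus a smooth positive
#' baseline; finally Rician noise — the magnitude of the signal plus a
#' complex Gaussian, \eqn{\sqrt{(x+n_1)^2 + n_2^2}} — is added with sigma
#' set so that the subject's contrast-to-noise ratio (peak noise-free signal
#' deviation over sigma) equals a draw from `cnr_range`. The full ground
#' truth is returned.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_dataset`: list with `config`,
#'   `template_spatial` (height x width x component array, unjittered) and
#'   `subjects`, one entry per subject containing `data` and `noise_free`
#'   (height x width x time arrays), `spatial` (height x width x component),
#'   `events` and `amplitudes` and `tc` (time x component matrices), `cnr`
#'   and `sigma`.
#' @examples
#' ds <- sim_dataset(sim_config(n_subjects = 1, grid = c(30, 30),
#'                              blob_sigma = 3, rng_seed = 7))
#' dim(ds$subjects[[1]]$data)
#' @export
sim_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- config$grid
  nc <- config$n_components
  centers <- component_centers(grid, nc)
  min_d <- if (nc > 1) min(stats::dist(centers)) else Inf
  if (min_d < 2 * config$blob_sigma) {
    abort("`grid` is too small to place the components without heavy overlap; enlarge the grid or shrink `blob_sigma`.")
  }
  template <- vapply(seq_len(nc),
                     function(c) gaussian_blob(grid, centers[c, ],
                                               config$blob_sigma),
                     matrix(0, grid[1], grid[2]))
  kernel <- hrf_kernel(config$tr)
  baseline <- baseline_field(grid)
  jit <- config$spatial_jitter
  c0 <- (grid + 1) / 2

  subjects <- purrr::map(seq_len(config$n_subjects), function(s) {
    seed_s <- child_seed(config$rng_seed, 100L + s)
    withr::with_seed(seed_s, {
      theta <- runif(1, -jit$rotate, jit$rotate) * pi / 180
      shift <- runif(2, -jit$translate, jit$translate)
      spread <- config$blob_sigma * (1 + runif(1, -jit$spread, jit$spread))
      rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
      cen_s <- t(rot %*% (t(centers) - c0) + c0 + shift)
      cnr <- runif(1, config$cnr_range[1], config$cnr_range[2])
    })
    spatial <- vapply(seq_len(nc),
                      function(c) gaussian_blob(grid, cen_s[c, ], spread),
                      matrix(0, grid[1], grid[2]))
    trains <- purrr::map(seq_len(nc), function(c) {
      sim_event_train(config, c, seed = child_seed(seed_s, c))
    })
    amplitudes <- vapply(trains, `[[`, numeric(config$n_time), "amplitude")
    events <- vapply(trains, `[[`, integer(config$n_time), "train")
    tc <- apply(amplitudes, 2, convolve_hrf, kernel = kernel)
    # noise-free data: sum_c map_c(v) * tc_c(n) + baseline(v)
    flat_maps <- matrix(spatial, nrow = prod(grid), ncol = nc)
    noise_free <- array(flat_maps %*% t(tc), dim = c(grid, config$n_time)) +
      as.vector(baseline)
    peak <- max(abs(sweep(noise_free, c(1, 2), baseline)))
    sigma <- if (peak > 0) peak / cnr else 0
    data <- rician(noise_free, sigma, child_seed(seed_s, 999L))
    list(data = data, noise_free = noise_free, spatial = spatial,
         events = events, amplitudes = amplitudes, tc = tc,
         cnr = cnr, sigma = sigma)
  })
  structure(list(config = config, template_spatial = template,
                 baseline = baseline, subjects = subjects),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<sim_dataset> %d subject(s), %d x %d grid, %d time points (TR %g s), %d components\n",
    cfg$n_subjects, cfg$grid[1], cfg$grid[2], cfg$n_time, cfg$tr,
    cfg$n_components))
  invisible(x)
}

#' Active-area mask of a simulated component
#'
#' Voxels where the (template or subject) spatial map exceeds `level` times
#' its peak — by default the full-width-at-half-maximum region of the
#' Gaussian blob, the simulator's notion of a component's active area.
#'
#' @param spatial height x width x component array of spatial maps.
#' @param component Component index.
#' @param level Fraction of the peak (default 0.5).
#' @return Logical height x width matrix.
#' @export
component_mask <- function(spatial, component, level = 0.5) {
  m <- spatial[, , component]
  m >= level * max(m)
}

#' Append event-free noise frames to a simulated dataset
#'
#' Extends every subject's time course with `fraction` additional time
#' points containing only the baseline plus Rician noise at the subject's
#' own noise level — frames with no event-related structure. Used to probe
#' how frame selection copes with unstructured volumes: HSNR-based
#' selection should skip them, all-frames selection cannot.
#'
#' @param dataset A [sim_dataset()].
#' @param fraction Number of appended frames as a fraction of `n_time`
#'   (default 0.3).
#' @param seed Seed for the appended noise (default: derived from the
#'   dataset's config seed).
#' @return A list of per-subject arrays (height x width x extended time);
#'   the original frames come first. The attribute `n_structured` records
#'   the original `n_time`.
#' @export
sim_augment_noise_frames <- function(dataset, fraction = 0.3, seed = NULL) {
  stopifnot(inherits(dataset, "sim_dataset"))
  check_scalar(fraction, "fraction", lower = 0)
  cfg <- dataset$config
  n_extra <- round(fraction * cfg$n_time)
  seed <- seed %||% child_seed(cfg$rng_seed, 555L)
  out <- purrr::imap(dataset$subjects, function(sub, s) {
    flat_base <- array(rep(as.vector(dataset$baseline), n_extra),
                       dim = c(cfg$grid, n_extra))
    noise <- rician(flat_base, sub$sigma, child_seed(seed, s))
    arr <- array(0, dim = c(cfg$grid, cfg$n_time + n_extra))
    arr[, , seq_len(cfg$n_time)] <- sub$data
    arr[, , cfg$n_time + seq_len(n_extra)] <- noise
    arr
  })
  attr(out, "n_structured") <- cfg$n_time
  out
}

#' Simulate a 1D event time course fixture
#'
#' Places unit impulses at the given onsets, convolves with the double-gamma
#' HRF and adds white Gaussian noise — the minimal fixture for
#' onset-recovery tests.
#'
#' @param onsets Integer onset indices in `[1, n_time]` (1-based).
#' @param n_time Series length.
#' @param tr Repetition time in seconds.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Seed for the noise (ignored when `noise_sd = 0`).
#' @return List with `series` (numeric, length `n_time`), `onsets` (the
#'   ground truth, unchanged) and `tr`.
#' @export
sim_event_series <- function(onsets, n_time, tr = 2, noise_sd = 0, seed = 1L) {
  check_scalar(n_time, "n_time", lower = 2, integerish = TRUE)
  check_scalar(tr, "tr", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  onsets <- as.integer(onsets)
  if (length(onsets) > 0 && (any(onsets < 1L) || any(onsets > n_time))) {
    abort("`onsets` must lie within [1, n_time].")
  }
  impulse <- numeric(n_time)
  impulse[onsets] <- 1
  series <- convolve_hrf(impulse, hrf_kernel(tr))
  if (noise_sd > 0) {
    series <- series + withr::with_seed(seed, rnorm(n_time, 0, noise_sd))
  }
  list(series = series, onsets = sort(onsets), tr = tr)
}
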