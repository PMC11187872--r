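#' Conditional rate of matched BOLD events
#'
#' Fraction of seed onsets that find a matching target onset at a delay of at
#' most `max_shift` TR: \eqn{CR = \frac{1}{n_s} \sum_{i=0}^{I} n_t^i}, where
#' \eqn{n_t^i} counts target onsets matched at the i-th shift. Coactivated
#' voxel pairs give CR close to 1, non-coactivated pairs low CR. Only
#' target-delayed (non-negative) shifts are considered: the haemodynamic
#' delay makes the target respond at or after the seed.
#'
#' With `unique_matching = TRUE` (default) matching is one-to-one and greedy
#' — smallest shift first, earliest onset first, each seed and target onset
#' consumed at most once — which bounds CR to `[0, 1]`. With
#' `unique_matching = FALSE` the literal per-shift counts are summed without
#' consuming onsets, and CR may exceed 1.
#'
#' @param seed_onsets,target_onsets Integer onset index vectors (e.g. from
#'   [detect_onsets()]). The seed train must be non-empty.
#' @param max_shift Maximum delay in TR for a match (default 2).
#' @param unique_matching One-to-one matching (default `TRUE`).
#' @return A single number; in `[0, 1]` under unique matching.
#' @examples
#' conditional_rate(c(3, 10, 20), c(3, 11, 40)) # 2/3
#' @export
conditional_rate <- function(seed_onsets, target_onsets, max_shift = 2L,
                             unique_matching = TRUE) {
  check_scalar(max_shift, "max_shift", lower = 0, integerish = TRUE)
  check_flag(unique_matching, "unique_matching")
  if (length(seed_onsets) == 0) {
    abort("CR is undefined for an empty seed onset train.")
  }
  seed_onsets <- sort(as.integer(seed_onsets))
  target_onsets <- sort(as.integer(target_onsets))
  n_s <- length(seed_onsets)
  if (length(target_onsets) == 0) return(0)
  if (unique_matching) {
    seed_free <- rep(TRUE, n_s)
    targ_free <- rep(TRUE, length(target_onsets))
    matches <- 0L
    for (i in 0:max_shift) {
      for (j in which(seed_free)) {
        k <- which(targ_free & target_onsets == seed_onsets[j] + i)
        if (length(k) > 0) {
          seed_free[j] <- FALSE
          targ_free[k[1]] <- FALSE
          matches <- matches + 1L
        }
      }
    }
    matches / n_s
  } else {
    total <- sum(vapply(0:max_shift, function(i) {
      sum(target_onsets %in% (seed_onsets + i))
    }, numeric(1)))
    total / n_s
  }
}

#' Mean correlation over high-SNR segments
#'
#' Averages the per-segment Pearson correlation between seed and target over
#' the seed's HSNR windows:
#' \eqn{\rho_{hsnr} = \frac{1}{N} \sum_s \rho_s}, with each \eqn{\rho_s}
#' computed from the segment samples after removing the segment means and
#' normalising by the segment standard deviations (consistent degrees of
#' freedom, so self-correlation is exactly 1). Segments where either side
#' has zero variance are skipped and N reduced.
#'
#' @param seed_series,target_series Numeric time courses of equal length.
#' @param segments Segment tibble from [hsnr_segments()].
#' @return Mean segment correlation in `[-1, 1]`.
#' @export
hsnr_correlation <- function(seed_series, target_series, segments) {
  check_numeric_series(seed_series, "seed_series")
  check_numeric_series(target_series, "target_series")
  if (length(seed_series) != length(target_series)) {
    abort("Seed and target series must have the same length.")
  }
  if (nrow(segments) == 0) {
    abort("HSNR correlation is undefined for an empty segment set.")
  }
  rho <- purrr::map2_dbl(segments$start, segments$length, function(st, len) {
    idx <- seq.int(st, st + len - 1L)
    a <- seed_series[idx]
    b <- target_series[idx]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  })
  rho <- rho[!is.na(rho)]
  if (length(rho) == 0) {
    abort("All HSNR segments are degenerate (zero variance).")
  }
  mean(rho)
}

# Flatten an array with trailing time dimension to voxels x time, with
# bookkeeping for the spatial dims.
as_voxel_matrix <- function(data) {
  d <- dim(data)
  if (is.null(d) || length(d) < 2) {
    abort("`data` must be an array with a trailing time dimension.")
  }
  sp <- d[-length(d)]
  list(mat = matrix(data, nrow = prod(sp), ncol = d[length(d)]), dim = sp)
}

default_mask <- function(mat, dim) {
  v <- matrixStats_rowVars(mat)
  array(v > 0, dim = dim)
}

# Row variances without a matrixStats dependency.
matrixStats_rowVars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  (rowSums(m^2) - n * mu^2) / (n - 1)
}

#' Seed-based static functional connectivity map
#'
#' Computes a per-voxel connectivity value against a seed time course with
#' one of four metrics: full-series Pearson correlation (`"correlation"`),
#' conditional rate of ZFR- or threshold-detected onsets (`"cr_zfr"`,
#' `"cr_threshold"`), or the mean correlation over the seed's ZFR-derived
#' high-SNR segments (`"hsnr"`). For the conditional-rate metrics, onsets
#' are detected at the seed and at every mask voxel and [conditional_rate()]
#' evaluated per voxel; voxels where the detector fires nowhere get CR 0.
#' For `"hsnr"`, the seed's segments fix the temporal windows applied to
#' every target.
#'
#' @param data Array whose last dimension is time (height x width x time or
#'   x by y by z by time).
#' @param seed Either a voxel index vector (one entry per spatial dimension,
#'   1-based) or a numeric seed time course of matching length.
#' @param metric One of `"correlation"`, `"cr_zfr"`, `"cr_threshold"`,
#'   `"hsnr"`.
#' @param mask Logical array over the spatial dimensions; default keeps
#'   voxels with nonzero variance.
#' @param wz,w,n_cascades,threshold_sd,max_shift,unique_matching Detector and
#'   matching parameters, see [detect_onsets()], [hsnr_segments()] and
#'   [conditional_rate()].
#' @param all_points For the `"cr_threshold"` metric, use every
#'   supra-threshold sample as an event (default `TRUE`, the literal
#'   point-process comparator); `FALSE` uses upward threshold crossings.
#' @param tr Repetition time in seconds (needed for the band-pass).
#' @param preprocess Band-pass every time course to 0.01-0.1 Hz before
#'   computing the metric (default `TRUE`, the standard resting-state
#'   preprocessing; detection requires a zero-centred band-limited series).
#' @return An object of class `fc_map`: list with `values` (numeric over
#'   mask voxels), `mask`, `dim`, `metric`, `seed` and `params`.
#' @export
fc_map <- function(data, seed,
                   metric = c("correlation", "cr_zfr", "cr_threshold", "hsnr"),
                   mask = NULL, wz = 9L, w = 6L, n_cascades = 1L,
                   threshold_sd = 1, max_shift = 2L, unique_matching = TRUE,
                   all_points = TRUE, tr = 2, preprocess = TRUE) {
  metric <- match.arg(metric)
  check_flag(preprocess, "preprocess")
  vm <- as_voxel_matrix(data)
  n_time <- ncol(vm$mat)
  if (is.null(mask)) {
    mask <- default_mask(vm$mat, vm$dim)
  }
  if (!identical(dim(mask), as.integer(vm$dim)) &&
      !identical(dim(mask), vm$dim)) {
    abort("`mask` dimensions must match the spatial dimensions of `data`.")
  }
  seed_is_coord <- length(seed) == length(vm$dim) &&
    all(seed == round(seed)) && n_time != length(vm$dim)
  if (is.numeric(seed) && length(seed) == n_time && !seed_is_coord) {
    seed_series <- as.numeric(seed)
    seed_id <- NULL
  } else if (seed_is_coord) {
    if (any(seed < 1) || any(seed > vm$dim)) {
      abort("`seed` voxel lies outside the data grid.")
    }
    seed_flat <- as.integer(sum((seed - 1) * cumprod(c(1, vm$dim[-length(vm$dim)]))) + 1)
    if (!mask[seed_flat]) abort("`seed` voxel lies outside the mask.")
    seed_series <- vm$mat[seed_flat, ]
    seed_id <- as.integer(seed)
  } else {
    abort("`seed` must be a voxel coordinate or a seed time course.")
  }
  vox <- which(as.vector(mask))
  target <- vm$mat[vox, , drop = FALSE]
  if (preprocess) {
    seed_series <- bandpass(seed_series, tr = tr)
    target <- bandpass_rows(target, tr = tr)
  }
  values <- switch(
    metric,
    correlation = as.numeric(cor(seed_series, t(target))),
    cr_zfr = ,
    cr_threshold = {
      det <- if (metric == "cr_zfr") "zfr" else "threshold"
      ap <- det == "threshold" && all_points
      seed_on <- detect_onsets(seed_series, method = det, wz = wz,
                               n_cascades = n_cascades,
                               threshold_sd = threshold_sd, all_points = ap)
      if (length(seed_on) == 0) {
        abort("No onsets detected in the seed time course; CR map undefined.")
      }
      apply(target, 1, function(ts) {
        on <- tryCatch(
          detect_onsets(ts, method = det, wz = wz, n_cascades = n_cascades,
                        threshold_sd = threshold_sd, all_points = ap),
          error = function(e) integer())
        if (length(on) == 0) 0 else
          conditional_rate(seed_on, on, max_shift = max_shift,
                           unique_matching = unique_matching)
      })
    },
    hsnr = {
      seed_on <- detect_onsets(seed_series, method = "zfr", wz = wz,
                               n_cascades = n_cascades)
      segs <- hsnr_segments(seed_on, w = w, n_time = n_time)
      if (nrow(segs) == 0) {
        abort("No HSNR segments at the seed; map undefined.")
      }
      apply(target, 1, function(ts) {
        tryCatch(hsnr_correlation(seed_series, ts, segs),
                 error = function(e) NA_real_)
      })
    })
  structure(list(values = values, mask = mask, dim = vm$dim, metric = metric,
                 seed = seed_id, seed_series = seed_series,
                 params = list(wz = wz, w = w, n_cascades = n_cascades,
                               threshold_sd = threshold_sd,
                               all_points = all_points,
                               max_shift = max_shift,
                               unique_matching = unique_matching),
                 binary = NULL),
            class = "fc_map")
}

#' @export
print.fc_map <- function(x, ...) {
  cat(sprintf("<fc_map> metric %s over %d mask voxels (grid %s)\n",
              x$metric, length(x$values), paste(x$dim, collapse = " x ")))
  if (!is.null(x$binary)) {
    cat(sprintf("  post-processed: %d voxels retained\n", sum(x$binary)))
  }
  invisible(x)
}

# Connected-component labelling on a logical array (2D or 3D).
# connectivity: 6/18/26 for 3D (face/edge/corner); for 2D arrays 6 -> 4-
# and 18/26 -> 8-neighbourhood.
label_components <- function(active, connectivity = 26L) {
  d <- dim(active)
  nd <- length(d)
  if (!nd %in% c(2L, 3L)) abort("`active` must be a 2D or 3D logical array.")
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  ord <- rowSums(abs(offs))
  max_ord <- switch(as.character(connectivity),
                    "6" = 1L, "18" = 2L, "26" = nd,
                    abort("`connectivity` must be 6, 18 or 26."))
  offs <- offs[ord > 0 & ord <= max_ord, , drop = FALSE]
  idx <- which(active)
  if (length(idx) == 0) return(array(0L, dim = d))
  coord <- arrayInd(idx, d)
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)
  mult <- cumprod(c(1, d[-nd]))
  edges <- purrr::map(seq_len(nrow(offs)), function(i) {
    nb <- sweep(coord, 2, offs[i, ], `+`)
    ok <- rowSums(nb < 1) == 0 & rowSums(sweep(nb, 2, d, `>`)) == 0
    if (!any(ok)) return(NULL)
    flat <- as.integer((nb[ok, , drop = FALSE] - 1) %*% mult + 1)
    live <- active[flat]
    if (!any(live)) return(NULL)
    cbind(which(ok)[live], pos[flat[live]])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(idx), seq_along(idx))), directed = FALSE)
  memb <- igraph::components(g)$membership
  lab <- array(0L, dim = d)
  lab[idx] <- as.integer(memb)
  lab
}

#' Threshold and cluster-filter a connectivity map
#'
#' Standard map post-processing: min-max normalise the values over the mask,
#' keep the top `top_fraction` of voxels (the cutoff is the
#' `ceiling(top_fraction * V)`-th largest value; ties at the cutoff are
#' kept), then drop connected components smaller than `min_cluster` voxels
#' under the chosen neighbourhood.
#'
#' @param map An [fc_map()] object, or a numeric array of map values.
#' @param top_fraction Fraction of mask voxels to retain (default 0.2).
#' @param min_cluster Minimum connected-component size in voxels
#'   (default 16).
#' @param connectivity Neighbourhood for clustering: 6, 18 or 26 (default 26;
#'   for 2D maps 26 means the 8-neighbourhood, 6 the 4-neighbourhood).
#' @param mask Logical array (only when `map` is a plain array).
#' @return For an `fc_map` input, the same object with `binary` (logical
#'   array) and `post_params` filled in; for an array input, the binary
#'   logical array.
#' @export
postprocess_map <- function(map, top_fraction = 0.2, min_cluster = 16L,
                            connectivity = 26L, mask = NULL) {
  check_scalar(top_fraction, "top_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (top_fraction >= 1) abort("`top_fraction` must be < 1.")
  check_scalar(min_cluster, "min_cluster", lower = 1, integerish = TRUE)
  is_obj <- inherits(map, "fc_map")
  if (is_obj) {
    values <- map$values
    mask <- map$mask
    dims <- map$dim
  } else {
    if (is.null(mask)) mask <- array(TRUE, dim = dim(map))
    dims <- dim(map)
    values <- map[as.vector(mask)]
  }
  values[is.na(values)] <- min(values, na.rm = TRUE)
  rng <- range(values)
  if (rng[1] == rng[2]) {
    abort("Map is constant over the mask; post-processing is undefined.")
  }
  norm <- (values - rng[1]) / (rng[2] - rng[1])
  k <- ceiling(top_fraction * length(norm))
  cutoff <- sort(norm, decreasing = TRUE)[k]
  active <- array(FALSE, dim = dims)
  active[which(as.vector(mask))] <- norm >= cutoff
  lab <- label_components(active, connectivity = connectivity)
  keep <- which(tabulate(lab[lab > 0]) >= min_cluster)
  binary <- array(lab %in% keep, dim = dims)
  if (is_obj) {
    map$binary <- binary
    map$post_params <- list(top_fraction = top_fraction,
                            min_cluster = min_cluster,
                            connectivity = connectivity)
    map
  } else {
    binary
  }
}

#' Average time courses within labelled regions of interest
#'
#' @param data Array with trailing time dimension.
#' @param labels Integer array over the spatial dimensions; 0 (or `NA`) is
#'   background. Labels with no voxels inside the grid are reported with a
#'   warning and skipped.
#' @return Time x ROI matrix; column names are the label values.
#' @export
roi_timecourses <- function(data, labels) {
  vm <- as_voxel_matrix(data)
  if (length(labels) != nrow(vm$mat)) {
    abort("`labels` must match the spatial grid of `data`.")
  }
  lab <- as.vector(labels)
  lab[is.na(lab)] <- 0L
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) abort("`labels` contains no foreground ROI.")
  out <- vapply(ids, function(id) {
    colMeans(vm$mat[lab == id, , drop = FALSE])
  }, numeric(ncol(vm$mat)))
  colnames(out) <- ids
  out
}
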