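#' Tidy a connectivity map
#'
#' One row per mask voxel with its grid coordinates and map value; the
#' post-processed binary state is included when present.
#'
#' @param x An [fc_map()] object.
#' @param ... Unused.
#' @return A tibble with the voxel coordinates (`x`, `y`[, `z`]), `value`
#'   and optionally `active`.
#' @export
tidy.fc_map <- function(x, ...) {
  vox <- which(as.vector(x$mask))
  coords <- arrayInd(vox, x$dim)
  colnames(coords) <- c("x", "y", "z")[seq_len(ncol(coords))]
  out <- dplyr::bind_cols(tibble::as_tibble(coords),
                          tibble::tibble(value = x$values))
  if (!is.null(x$binary)) out$active <- as.vector(x$binary)[vox]
  out
}

#' @describeIn tidy.fc_map One-row summary: metric, voxel count, mean and
#'   range of the map values.
#' @export
glance.fc_map <- function(x, ...) {
  tibble::tibble(metric = x$metric, n_voxels = length(x$values),
                 mean = mean(x$values, na.rm = TRUE),
                 min = min(x$values, na.rm = TRUE),
                 max = max(x$values, na.rm = TRUE),
                 n_active = if (is.null(x$binary)) NA_integer_ else
                   sum(x$binary))
}

#' Tidy a CAP set
#'
#' One row per (cap, voxel) with the centroid value.
#'
#' @param x A [kmeans_cosine()] `cap_set`.
#' @param ... Unused.
#' @return A tibble with `cap`, `voxel`, `value`.
#' @export
tidy.cap_set <- function(x, ...) {
  tibble::tibble(cap = rep(seq_len(x$k), each = ncol(x$centroids)),
                 voxel = rep(seq_len(ncol(x$centroids)), times = x$k),
                 value = as.vector(t(x$centroids)))
}

#' @describeIn tidy.cap_set One-row summary: K, frame count, distortion.
#' @export
glance.cap_set <- function(x, ...) {
  tibble::tibble(k = x$k, n_frames = sum(x$sizes),
                 distortion = x$distortion,
                 min_size = min(x$sizes), max_size = max(x$sizes))
}

#' Tidy a CAP stability analysis
#'
#' Per-CAP summary joining the stability (mean/sd Jaccard over iteration
#' pairs), the dwell-time spread and the percentage fractional occupancy.
#'
#' @param x A [cap_stability()] object.
#' @param ... Unused.
#' @return A tibble with one row per CAP.
#' @export
tidy.cap_stability <- function(x, ...) {
  jac <- x$jaccard |>
    dplyr::group_by(.data$cap) |>
    dplyr::summarise(mean_jaccard = mean(.data$jaccard),
                     sd_jaccard = sd(.data$jaccard), .groups = "drop")
  dw <- x$dwell |>
    dplyr::group_by(.data$cap) |>
    dplyr::summarise(mean_dwell = mean(.data$frames),
                     sd_dwell = sd(.data$frames), .groups = "drop")
  jac |>
    dplyr::left_join(dw, by = "cap") |>
    dplyr::left_join(x$pfo, by = "cap")
}

#' @describeIn tidy.cap_stability One-row summary: overall mean/sd Jaccard
#'   and total PFO.
#' @export
glance.cap_stability <- function(x, ...) {
  tibble::tibble(k = x$params$k, n_it = x$params$n_it,
                 mean_jaccard = mean(x$jaccard$jaccard),
                 sd_jaccard = sd(x$jaccard$jaccard),
                 total_pfo = sum(x$pfo$pfo))
}

#' Tidy a score partition
#'
#' @param x A [score_table()] `score_partition`.
#' @param ... Unused.
#' @return The per-pair score tibble.
#' @export
tidy.score_partition <- function(x, ...) x$scores

#' @describeIn tidy.score_partition One row per group with mean, sd and the
#'   coactivation minus non-coactivation gap.
#' @export
glance.score_partition <- function(x, ...) {
  s <- x$summary
  gap <- s$mean[s$group == "coactivation"] -
    s$mean[s$group == "non-coactivation"]
  tibble::tibble(metric = x$metric,
                 coactivation_mean = s$mean[s$group == "coactivation"],
                 coactivation_sd = s$sd[s$group == "coactivation"],
                 noncoactivation_mean = s$mean[s$group == "non-coactivation"],
                 noncoactivation_sd = s$sd[s$group == "non-coactivation"],
                 difference = gap,
                 fisher_j = fisher_discriminant(x))
}
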