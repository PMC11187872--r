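#' Plot a 2D connectivity map
#'
#' Raster of the map values over the slice; post-processed maps show the
#' surviving voxels. 3D maps are shown as the requested axial slice.
#'
#' @param object An [fc_map()] object.
#' @param binary Plot the post-processed binary map instead of the values.
#' @param slice Slice index along the third axis for 3D maps.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fc_map <- function(object, binary = FALSE, slice = NULL, ...) {
  df <- tidy(object)
  if ("z" %in% names(df)) {
    slice <- slice %||% ceiling(object$dim[3] / 2)
    df <- dplyr::filter(df, .data$z == slice)
  }
  fill <- if (binary && "active" %in% names(df)) "active" else "value"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$x,
                                   fill = .data[[fill]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = sprintf("%s map", object$metric),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot coactivation patterns as slice rasters
#'
#' One facet per CAP over the 2D grid (or a slice of a 3D grid).
#'
#' @param object A [kmeans_cosine()] `cap_set` carrying spatial bookkeeping.
#' @param slice Slice index for 3D grids.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cap_set <- function(object, slice = NULL, ...) {
  if (is.null(object$dim)) {
    abort("This cap_set carries no voxel grid; plot the centroids manually.")
  }
  msk <- object$mask %||% array(TRUE, dim = object$dim)
  vox <- which(as.vector(msk))
  coords <- arrayInd(vox, object$dim)
  colnames(coords) <- c("x", "y", "z")[seq_len(ncol(coords))]
  df <- purrr::map_dfr(seq_len(object$k), function(c) {
    dplyr::bind_cols(tibble::as_tibble(coords),
                     tibble::tibble(cap = c, value = object$centroids[c, ]))
  })
  if ("z" %in% names(df)) {
    slice <- slice %||% ceiling(object$dim[3] / 2)
    df <- dplyr::filter(df, .data$z == slice)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$x,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~cap, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot CAP stability as per-CAP Jaccard distributions
#'
#' Boxplot of the pairwise Jaccard similarities across resampling
#' iterations, one box per CAP.
#'
#' @param object A [cap_stability()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cap_stability <- function(object, ...) {
  ggplot2::ggplot(object$jaccard,
                  ggplot2::aes(x = factor(.data$cap), y = .data$jaccard)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "CAP", y = "Jaccard similarity") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a detected onset train over its time course
#'
#' Line plot of the series with vertical marks at the detected onsets —
#' the quick visual check that the detector is firing where events rise.
#'
#' @param x Numeric time course.
#' @param onsets Integer onset indices, e.g. from [detect_onsets()].
#' @param tr Repetition time in seconds (x axis scaling; default 1 sample).
#' @return A ggplot object.
#' @export
plot_onsets <- function(x, onsets, tr = 1) {
  df <- tibble::tibble(time = (seq_along(x) - 1) * tr, value = x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = (onsets - 1) * tr,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = if (tr == 1) "sample" else "time (s)",
                  y = "BOLD amplitude") +
    ggplot2::theme_minimal()
}
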