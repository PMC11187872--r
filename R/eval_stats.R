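#' Fisher discriminant ratio between score groups
#'
#' \eqn{J = (\mu_a - \mu_n)^2 / (\sigma_a^2 + \sigma_n^2)}: squared gap
#' between the mean coactivation and non-coactivation scores over the sum of
#' their population variances. Larger J means the metric separates
#' within-network from between-network pairs better. J is invariant to
#' adding a constant to all scores and to positive rescaling.
#'
#' @param coactivation,noncoactivation Numeric score vectors (>= 2 each), or
#'   a single `score_partition` from [score_table()] as the first argument.
#' @return The ratio J (single number).
#' @export
fisher_discriminant <- function(coactivation, noncoactivation = NULL) {
  if (inherits(coactivation, "score_partition")) {
    sc <- coactivation$scores
    noncoactivation <- sc$score[!sc$coactivation]
    coactivation <- sc$score[sc$coactivation]
  }
  if (length(coactivation) < 2 || length(noncoactivation) < 2) {
    abort("Both score groups need at least 2 values.")
  }
  pop_var <- function(x) mean((x - mean(x))^2)
  denom <- pop_var(coactivation) + pop_var(noncoactivation)
  if (denom == 0) abort("J is undefined: both groups have zero variance.")
  (mean(coactivation) - mean(noncoactivation))^2 / denom
}

#' Spatial correlation between two connectivity maps
#'
#' Pearson correlation of the map values over the (shared) mask.
#'
#' @param map_a,map_b [fc_map()] objects on the same mask, or numeric
#'   vectors/arrays of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
spatial_correlation <- function(map_a, map_b) {
  va <- if (inherits(map_a, "fc_map")) map_a$values else as.numeric(map_a)
  vb <- if (inherits(map_b, "fc_map")) map_b$values else as.numeric(map_b)
  if (length(va) != length(vb)) {
    abort("Maps must be defined on the same mask.")
  }
  keep <- is.finite(va) & is.finite(vb)
  if (sd(va[keep]) == 0 || sd(vb[keep]) == 0) {
    abort("Spatial correlation is undefined for a constant map.")
  }
  cor(va[keep], vb[keep])
}

score_pair <- function(a, b, metric, wz, w, n_cascades, threshold_sd,
                       max_shift, unique_matching, all_points = TRUE) {
  switch(
    metric,
    correlation = cor(a, b),
    cr_zfr = ,
    cr_threshold = {
      det <- if (metric == "cr_zfr") "zfr" else "threshold"
      ap <- det == "threshold" && all_points
      on_a <- detect_onsets(a, method = det, wz = wz,
                            n_cascades = n_cascades,
                            threshold_sd = threshold_sd, all_points = ap)
      on_b <- detect_onsets(b, method = det, wz = wz,
                            n_cascades = n_cascades,
                            threshold_sd = threshold_sd, all_points = ap)
      # CR is direction-dependent; ROI pair scores are symmetrised
      cr_dir <- function(s, t) {
        if (length(s) == 0) return(NA_real_)
        conditional_rate(s, t, max_shift = max_shift,
                         unique_matching = unique_matching)
      }
      mean(c(cr_dir(on_a, on_b), cr_dir(on_b, on_a)), na.rm = TRUE)
    },
    hsnr = {
      rho_dir <- function(s, t) {
        on <- detect_onsets(s, method = "zfr", wz = wz,
                            n_cascades = n_cascades)
        segs <- hsnr_segments(on, w = w, n_time = length(s))
        if (nrow(segs) == 0) return(NA_real_)
        tryCatch(hsnr_correlation(s, t, segs), error = function(e) NA_real_)
      }
      mean(c(rho_dir(a, b), rho_dir(b, a)), na.rm = TRUE)
    })
}

#' Coactivation and non-coactivation scores between ROI time courses
#'
#' Scores every unordered pair of ROI time courses with the chosen
#' connectivity metric and partitions the pairs into coactivation scores
#' (both ROIs in the same functional network) and non-coactivation scores
#' (different networks). Direction-dependent metrics (conditional rate,
#' HSNR correlation) are symmetrised as the mean of both directions.
#'
#' @param roi_series Time x ROI numeric matrix, e.g. from
#'   [roi_timecourses()].
#' @param networks Network label per ROI (length = number of columns);
#'   at least two distinct networks are required.
#' @param metric `"correlation"`, `"cr_zfr"`, `"cr_threshold"` or `"hsnr"`.
#' @param wz,w,n_cascades,threshold_sd,max_shift,unique_matching Metric
#'   parameters, see [detect_onsets()] and [conditional_rate()].
#' @param all_points For the `"cr_threshold"` metric, use every
#'   supra-threshold sample as an event (default `TRUE`, the literal
#'   point-process comparator).
#' @param tr Repetition time in seconds (needed for the band-pass).
#' @param preprocess Band-pass every ROI series to 0.01-0.1 Hz before
#'   scoring (default `TRUE`).
#' @return An object of class `score_partition`: list with `scores` (tibble:
#'   roi_a, roi_b, network_a, network_b, coactivation, score), `metric`, and
#'   a `summary` tibble (group, n, mean, sd) mirroring the coactivation /
#'   non-coactivation layout.
#' @export
score_table <- function(roi_series, networks,
                        metric = c("correlation", "cr_zfr", "cr_threshold",
                                   "hsnr"),
                        wz = 9L, w = 6L, n_cascades = 1L, threshold_sd = 1,
                        max_shift = 2L, unique_matching = TRUE,
                        all_points = TRUE, tr = 2, preprocess = TRUE) {
  metric <- match.arg(metric)
  check_flag(preprocess, "preprocess")
  roi_series <- as.matrix(roi_series)
  if (preprocess) {
    roi_series <- apply(roi_series, 2, bandpass, tr = tr)
  }
  n_roi <- ncol(roi_series)
  if (length(networks) != n_roi) {
    abort("`networks` must have one label per ROI column.")
  }
  if (length(unique(networks)) < 2) {
    abort("At least two distinct networks are required.")
  }
  roi_names <- colnames(roi_series) %||% as.character(seq_len(n_roi))
  pairs <- utils::combn(n_roi, 2)
  scores <- purrr::map_dbl(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    tryCatch(
      score_pair(roi_series[, i], roi_series[, j], metric, wz, w,
                 n_cascades, threshold_sd, max_shift, unique_matching,
                 all_points = all_points),
      error = function(e) {
        abort(sprintf("Metric '%s' failed on ROI pair (%s, %s): %s",
                      metric, roi_names[i], roi_names[j],
                      conditionMessage(e)))
      })
  })
  tab <- tibble::tibble(
    roi_a = roi_names[pairs[1, ]], roi_b = roi_names[pairs[2, ]],
    network_a = networks[pairs[1, ]], network_b = networks[pairs[2, ]],
    coactivation = networks[pairs[1, ]] == networks[pairs[2, ]],
    score = scores)
  summary <- tab |>
    dplyr::group_by(group = ifelse(.data$coactivation, "coactivation",
                                   "non-coactivation")) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$score, na.rm = TRUE),
                     sd = sd(.data$score, na.rm = TRUE), .groups = "drop")
  structure(list(scores = tab, metric = metric, summary = summary),
            class = "score_partition")
}

#' @export
print.score_partition <- function(x, ...) {
  cat(sprintf("<score_partition> metric %s, %d ROI pairs\n", x$metric,
              nrow(x$scores)))
  print(x$summary)
  invisible(x)
}

#' Within- and between-component connectivity scores on simulated data
#'
#' The simulation-based evaluation of the four connectivity metrics. For
#' each subject and component, the active area is taken from the subject's
#' ground-truth spatial map (the half-maximum region), the seed is the mean
#' time course over that area, and the seed is scored against every active
#' voxel of the same component (within-network scores) and of every other
#' component (between-network scores). All series are band-passed first;
#' voxel onsets for the conditional-rate metrics are detected once per
#' voxel and reused.
#'
#' @param dataset A [sim_dataset()].
#' @param metrics Metrics to evaluate (default all four).
#' @param level Active-area threshold as a fraction of each map's peak
#'   (default 0.5).
#' @param wz,w,threshold_sd,max_shift Detector and matching parameters.
#' @param all_points Use the literal point process (all supra-threshold
#'   samples) for the threshold comparator (default `TRUE`).
#' @return A tibble with one row per (subject, component, metric, group)
#'   where group is `"within"` or `"between"`, carrying `mean_score` and
#'   `n_pairs`.
#' @export
sim_separation_scores <- function(dataset,
                                  metrics = c("correlation", "cr_threshold",
                                              "cr_zfr", "hsnr"),
                                  level = 0.5, wz = 9L, w = 6L,
                                  threshold_sd = 1, max_shift = 2L,
                                  all_points = TRUE) {
  stopifnot(inherits(dataset, "sim_dataset"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  cfg <- dataset$config
  purrr::imap_dfr(dataset$subjects, function(sub, s) {
    vm <- as_voxel_matrix(sub$data)
    masks <- purrr::map(seq_len(cfg$n_components), function(c) {
      which(as.vector(component_mask(sub$spatial, c, level = level)))
    })
    vox <- sort(unique(unlist(masks)))
    bp <- bandpass_rows(vm$mat[vox, , drop = FALSE], tr = cfg$tr)
    rownames(bp) <- vox
    row_of <- function(v) bp[match(v, vox), , drop = FALSE]
    need_cr <- any(c("cr_zfr", "cr_threshold") %in% metrics)
    onsets <- if (need_cr) {
      list(
        zfr = purrr::map(seq_len(nrow(bp)), function(i)
          detect_onsets(bp[i, ], method = "zfr", wz = wz)),
        threshold = purrr::map(seq_len(nrow(bp)), function(i)
          tryCatch(detect_onsets(bp[i, ], method = "threshold",
                                 threshold_sd = threshold_sd,
                                 all_points = all_points),
                   error = function(e) integer())))
    }
    purrr::map_dfr(seq_len(cfg$n_components), function(c) {
      seed_tc <- bandpass(colMeans(vm$mat[masks[[c]], , drop = FALSE]),
                          tr = cfg$tr)
      seed_on <- list(
        zfr = detect_onsets(seed_tc, method = "zfr", wz = wz),
        threshold = tryCatch(
          detect_onsets(seed_tc, method = "threshold",
                        threshold_sd = threshold_sd,
                        all_points = all_points),
          error = function(e) integer()))
      segs <- hsnr_segments(seed_on$zfr, w = w, n_time = cfg$n_time)
      score_vox <- function(metric, v) {
        ts <- row_of(v)
        switch(metric,
          correlation = as.numeric(cor(seed_tc, t(ts))),
          cr_zfr = ,
          cr_threshold = {
            det <- if (metric == "cr_zfr") "zfr" else "threshold"
            if (length(seed_on[[det]]) == 0) return(rep(NA_real_, length(v)))
            idx <- match(v, vox)
            purrr::map_dbl(idx, function(i) {
              on <- onsets[[det]][[i]]
              if (length(on) == 0) 0 else
                conditional_rate(seed_on[[det]], on, max_shift = max_shift)
            })
          },
          hsnr = {
            if (nrow(segs) == 0) return(rep(NA_real_, length(v)))
            purrr::map_dbl(seq_len(nrow(ts)), function(i)
              tryCatch(hsnr_correlation(seed_tc, ts[i, ], segs),
                       error = function(e) NA_real_))
          })
      }
      within_v <- masks[[c]]
      between_v <- sort(unlist(masks[-c]))
      purrr::map_dfr(metrics, function(m) {
        tibble::tibble(
          subject = s, component = c, metric = m,
          group = c("within", "between"),
          mean_score = c(mean(score_vox(m, within_v), na.rm = TRUE),
                         mean(score_vox(m, between_v), na.rm = TRUE)),
          n_pairs = c(length(within_v), length(between_v)))
      })
    })
  })
}

#' Paired t-test between two score vectors
#'
#' Standard paired t statistic with a two-sided p value. The degenerate
#' cases follow the convention for connectivity-score comparisons: identical
#' vectors give t = 0, p = 1; constant non-zero differences have no defined
#' t and raise an error.
#'
#' @param a,b Paired numeric vectors of equal length (>= 2).
#' @return A tibble with `statistic`, `p.value`, `estimate` (mean
#'   difference), `parameter` (df) and `conf.low`/`conf.high`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    abort("`a` and `b` must be paired vectors of equal length >= 2.")
  }
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(statistic = 0, p.value = 1, estimate = 0,
                            parameter = length(d) - 1L,
                            conf.low = 0, conf.high = 0))
    }
    abort("Differences are constant and non-zero; the paired t is undefined.")
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic),
                 p.value = tt$p.value,
                 estimate = unname(tt$estimate),
                 parameter = unname(tt$parameter),
                 conf.low = tt$conf.int[1], conf.high = tt$conf.int[2])
}
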