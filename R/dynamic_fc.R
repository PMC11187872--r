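#' Select fMRI frames for coactivation-pattern analysis
#'
#' Builds the frames-by-voxels matrix that CAP clustering operates on.
#' `mode = "all"` takes every frame of every subject. The HSNR modes keep
#' only frames inside high-SNR windows around detected BOLD events: onsets
#' are detected at every mask voxel (ZFR or threshold detector), each
#' voxel's HSNR union marks the frames it covers, and a frame is selected
#' when at least a `quorum` fraction of mask voxels cover it (for a
#' single-voxel mask this reduces to the plain HSNR union). Voxel time
#' courses are demeaned per subject before frames are extracted, so that
#' frame similarity reflects the event-related deviation rather than the
#' baseline.
#'
#' @param x A [sim_dataset()], or a list of per-subject arrays with trailing
#'   time dimension.
#' @param mode `"all"`, `"hsnr_zfr"` or `"hsnr_threshold"`.
#' @param mask Logical array over the spatial dimensions (default: all
#'   voxels).
#' @param quorum Minimum fraction of mask voxels whose HSNR union must cover
#'   a frame for it to be selected (default 0.1).
#' @param wz,w,n_cascades,threshold_sd Detector and window parameters.
#' @param tr Repetition time in seconds (needed for the band-pass).
#' @param preprocess Band-pass every voxel time course to 0.01-0.1 Hz before
#'   frame extraction and detection (default `TRUE`).
#' @return An object of class `frame_matrix`: list with `frames`
#'   (n_frames x n_maskvoxels), `provenance` (tibble: subject, time),
#'   `selection`, `mask` and `dim`.
#' @export
select_frames <- function(x, mode = c("all", "hsnr_zfr", "hsnr_threshold"),
                          mask = NULL, quorum = 0.1, wz = 9L, w = 6L,
                          n_cascades = 1L, threshold_sd = 1, tr = 2,
                          preprocess = TRUE) {
  mode <- match.arg(mode)
  check_scalar(quorum, "quorum", lower = 0, upper = 1)
  check_flag(preprocess, "preprocess")
  arrays <- if (inherits(x, "sim_dataset")) {
    purrr::map(x$subjects, "data")
  } else if (is.list(x)) {
    x
  } else {
    abort("`x` must be a sim_dataset or a list of per-subject arrays.")
  }
  vm1 <- as_voxel_matrix(arrays[[1]])
  if (is.null(mask)) mask <- array(TRUE, dim = vm1$dim)
  vox <- which(as.vector(mask))
  detector <- if (mode == "hsnr_zfr") "zfr" else "threshold"
  picked <- purrr::imap(arrays, function(arr, s) {
    vm <- as_voxel_matrix(arr)
    if (!identical(vm$dim, vm1$dim)) {
      abort("All subjects must share the same spatial grid.")
    }
    mat <- vm$mat[vox, , drop = FALSE]
    mat <- if (preprocess) bandpass_rows(mat, tr = tr) else
      mat - rowMeans(mat)
    n_time <- ncol(mat)
    keep <- if (mode == "all") {
      seq_len(n_time)
    } else {
      cover <- numeric(n_time)
      for (v in seq_len(nrow(mat))) {
        on <- tryCatch(
          detect_onsets(mat[v, ], method = detector, wz = wz,
                        n_cascades = n_cascades,
                        threshold_sd = threshold_sd),
          error = function(e) integer())
        u <- segment_union(hsnr_segments(on, w = w, n_time = n_time))
        cover[u] <- cover[u] + 1
      }
      which(cover / nrow(mat) >= quorum)
    }
    if (length(keep) == 0) {
      warn(sprintf("Subject %d contributes no frames under mode '%s'.",
                   s, mode))
    }
    list(frames = t(mat[, keep, drop = FALSE]),
         prov = tibble::tibble(subject = s, time = keep))
  })
  frames <- do.call(rbind, purrr::map(picked, "frames"))
  if (is.null(frames) || nrow(frames) == 0) {
    abort("Frame selection is empty.")
  }
  structure(list(frames = frames,
                 provenance = dplyr::bind_rows(purrr::map(picked, "prov")),
                 selection = mode, mask = mask, dim = vm1$dim),
            class = "frame_matrix")
}

#' @export
print.frame_matrix <- function(x, ...) {
  cat(sprintf("<frame_matrix> %d frames x %d voxels (selection: %s)\n",
              nrow(x$frames), ncol(x$frames), x$selection))
  invisible(x)
}

frame_data <- function(frames) {
  if (inherits(frames, "frame_matrix")) frames$frames else as.matrix(frames)
}

# k-means++ style seeding under cosine distance on unit-norm rows.
seed_centroids_pp <- function(xn, k) {
  n <- nrow(xn)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- pmax(1 - xn %*% xn[centers[1], ], 0)
  if (k > 1) for (j in 2:k) {
    p <- as.numeric(d2)
    if (sum(p) <= 0) p <- rep(1, n)
    centers[j] <- sample.int(n, 1, prob = p)
    d2 <- pmin(d2, pmax(1 - xn %*% xn[centers[j], ], 0))
  }
  xn[centers, , drop = FALSE]
}

#' K-means clustering of fMRI frames with cosine distance
#'
#' Partitions frames into K coactivation patterns by Lloyd iterations under
#' cosine distance (1 minus cosine similarity): frames are assigned to the
#' most similar centroid direction; centroids are the means of their member
#' frames (their direction is what matters — cosine distance is invariant
#' to positive rescaling of a frame). Seeding is k-means++-style under
#' cosine distance; the best of `n_restarts` seeded runs (lowest total
#' distortion) is returned, deterministically for a given `seed`.
#' Zero-norm frames cannot be placed on the unit sphere and are excluded
#' with a warning (their labels are `NA`).
#'
#' @param frames A `frame_matrix` from [select_frames()] or a plain
#'   n_frames x n_voxels matrix.
#' @param k Number of clusters (>= 2).
#' @param seed Master seed for seeding and restarts.
#' @param n_restarts Number of independent seeded runs (default 10).
#' @param max_iter,tol Lloyd iteration cap (default 300) and relative
#'   distortion tolerance (default 1e-6).
#' @return An object of class `cap_set`: `k`, `centroids` (K x voxels, raw
#'   member means), `labels` (per input frame; `NA` for excluded), `sizes`,
#'   `distortion` (sum of cosine distances to assigned centroids) and the
#'   spatial bookkeeping of the input when available.
#' @export
kmeans_cosine <- function(frames, k, seed = 1L, n_restarts = 10L,
                          max_iter = 300L, tol = 1e-6) {
  x <- frame_data(frames)
  check_scalar(k, "k", lower = 2, integerish = TRUE)
  check_scalar(n_restarts, "n_restarts", lower = 1, integerish = TRUE)
  nrm <- sqrt(rowSums(x^2))
  ok <- nrm > 0
  if (!all(ok)) {
    warn(sprintf("%d zero-norm frame(s) excluded from clustering.",
                 sum(!ok)))
  }
  xn <- x[ok, , drop = FALSE] / nrm[ok]
  n <- nrow(xn)
  if (n < k) abort("Fewer usable frames than clusters.")
  run_once <- function(run_seed) {
    withr::with_seed(run_seed, {
      cn <- seed_centroids_pp(xn, k)
      labels <- integer(n)
      dist_prev <- Inf
      for (it in seq_len(max_iter)) {
        sim <- xn %*% t(cn)
        labels <- max.col(sim, ties.method = "first")
        # refill empty clusters with the worst-fitted frame
        empty <- setdiff(seq_len(k), unique(labels))
        if (length(empty) > 0) {
          fit <- sim[cbind(seq_len(n), labels)]
          worst <- order(fit)[seq_along(empty)]
          labels[worst] <- empty
        }
        cm <- rowsum(xn, labels)[as.character(seq_len(k)), , drop = FALSE]
        cnrm <- sqrt(rowSums(cm^2))
        cnrm[cnrm == 0] <- 1
        cn_new <- cm / cnrm
        dist_now <- sum(1 - rowSums(xn * cn_new[labels, , drop = FALSE]))
        conv <- is.finite(dist_prev) &&
          abs(dist_prev - dist_now) <= tol * max(dist_prev, 1e-12)
        cn <- cn_new
        dist_prev <- dist_now
        if (conv) break
      }
      list(labels = labels, distortion = dist_prev)
    })
  }
  runs <- purrr::map(seq_len(n_restarts),
                     function(r) run_once(child_seed(seed, r)))
  best <- runs[[which.min(purrr::map_dbl(runs, "distortion"))]]
  # raw (unnormalised) centroids: mean frame of each cluster
  centroids <- rowsum(x[ok, , drop = FALSE],
                      best$labels)[as.character(seq_len(k)), , drop = FALSE] /
    tabulate(best$labels, k)
  labels_full <- rep(NA_integer_, nrow(x))
  labels_full[ok] <- best$labels
  structure(list(k = as.integer(k), centroids = centroids,
                 labels = labels_full,
                 sizes = tabulate(best$labels, k),
                 distortion = best$distortion,
                 mask = if (inherits(frames, "frame_matrix")) frames$mask,
                 dim = if (inherits(frames, "frame_matrix")) frames$dim,
                 provenance = if (inherits(frames, "frame_matrix"))
                   frames$provenance),
            class = "cap_set")
}

#' @export
print.cap_set <- function(x, ...) {
  cat(sprintf("<cap_set> K = %d over %d frames, distortion %.4g\n",
              x$k, sum(x$sizes), x$distortion))
  invisible(x)
}

#' Pick K on a distortion curve
#'
#' `rule = "knee"` (default) selects the point of maximum deviation from the
#' chord joining the endpoints of the min-max-normalised distortion curve —
#' the elbow. `rule = "min_distortion"` takes the literal minimum, which for
#' a non-increasing distortion curve is the largest K.
#'
#' @param k Integer vector of candidate K.
#' @param distortion Distortion at each K.
#' @param rule `"knee"` or `"min_distortion"`.
#' @return The selected K.
#' @export
elbow_k <- function(k, distortion, rule = c("knee", "min_distortion")) {
  rule <- match.arg(rule)
  if (length(k) != length(distortion) || length(k) == 0) {
    abort("`k` and `distortion` must be non-empty and of equal length.")
  }
  if (rule == "min_distortion" || length(k) < 3) {
    return(k[which.min(distortion)])
  }
  kn <- (k - min(k)) / max(max(k) - min(k), 1)
  rng <- range(distortion)
  dn <- if (rng[1] == rng[2]) rep(0, length(distortion)) else
    (distortion - rng[1]) / (rng[2] - rng[1])
  # distance below the chord from (kn[1], dn[1]) to (kn[end], dn[end])
  chord <- dn[1] + (dn[length(dn)] - dn[1]) * (kn - kn[1]) /
    max(kn[length(kn)] - kn[1], .Machine$double.eps)
  k[which.max(chord - dn)]
}

#' Scan K and choose the number of coactivation patterns
#'
#' Runs [kmeans_cosine()] for each K in `k_range`, records the distortion
#' curve, and selects K with [elbow_k()].
#'
#' @inheritParams kmeans_cosine
#' @param k_range Candidate K values (default 15:30).
#' @param rule Passed to [elbow_k()].
#' @return List with `k` (selected), `distortions` (tibble: k, distortion)
#'   and `rule`.
#' @export
choose_k_elbow <- function(frames, k_range = 15:30,
                           rule = c("knee", "min_distortion"), seed = 1L,
                           n_restarts = 5L) {
  rule <- match.arg(rule)
  if (length(k_range) == 0) abort("`k_range` must be non-empty.")
  k_range <- sort(unique(as.integer(k_range)))
  dist_k <- purrr::map_dbl(k_range, function(kk) {
    kmeans_cosine(frames, kk, seed = child_seed(seed, kk),
                  n_restarts = n_restarts)$distortion
  })
  list(k = elbow_k(k_range, dist_k, rule = rule),
       distortions = tibble::tibble(k = k_range, distortion = dist_k),
       rule = rule)
}

# Hungarian algorithm (shortest augmenting path), minimising total cost on a
# square matrix. Returns for each row the assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)
  v <- numeric(n + 1)     # columns 0..n, index j + 1; column 0 is virtual
  p <- integer(n + 1)     # p[j + 1]: row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1]] <- j
  assignment
}

#' Match coactivation patterns across two clusterings
#'
#' One-to-one assignment between the centroids of two [kmeans_cosine()]
#' solutions (equal K) maximising the summed spatial correlation of matched
#' pairs, solved exactly with the Hungarian algorithm.
#'
#' @param reference,other `cap_set` objects, or K x voxels centroid
#'   matrices, with equal K.
#' @return A tibble with columns `reference`, `other` (matched indices) and
#'   `correlation`.
#' @export
match_caps <- function(reference, other) {
  a <- if (inherits(reference, "cap_set")) reference$centroids else
    as.matrix(reference)
  b <- if (inherits(other, "cap_set")) other$centroids else as.matrix(other)
  if (nrow(a) != nrow(b)) abort("Both CAP sets must have the same K.")
  r <- cor(t(a), t(b))
  r[!is.finite(r)] <- 0
  asn <- solve_assignment(-r)
  tibble::tibble(reference = seq_len(nrow(a)), other = asn,
                 correlation = r[cbind(seq_len(nrow(a)), asn)])
}

#' Post-process coactivation patterns into binary maps
#'
#' Applies the standard map post-processing ([postprocess_map()]) to each
#' centroid: min-max normalisation, top-`top_fraction` intensity threshold,
#' and removal of connected components smaller than `min_cluster` voxels.
#' The spatial cluster filter needs the voxel grid; when the `cap_set`
#' carries none (plain-matrix input) and `dim` is not given, thresholding
#' alone is applied.
#'
#' @param caps A `cap_set`, or a K x voxels centroid matrix.
#' @param top_fraction,min_cluster,connectivity See [postprocess_map()].
#' @param dim Spatial dimensions of a voxel grid covering the columns
#'   (optional when `caps` carries them).
#' @param mask Logical array selecting the columns' voxels within `dim`.
#' @return K x voxels logical matrix of binarised CAPs.
#' @export
postprocess_caps <- function(caps, top_fraction = 0.2, min_cluster = 16L,
                             connectivity = 26L, dim = NULL, mask = NULL) {
  cent <- if (inherits(caps, "cap_set")) caps$centroids else as.matrix(caps)
  if (inherits(caps, "cap_set")) {
    dim <- dim %||% caps$dim
    mask <- mask %||% caps$mask
  }
  t(apply(cent, 1, function(v) {
    if (is.null(dim)) {
      rng <- range(v)
      if (rng[1] == rng[2]) {
        abort("Constant centroid; post-processing is undefined.")
      }
      norm <- (v - rng[1]) / (rng[2] - rng[1])
      cutoff <- sort(norm, decreasing = TRUE)[ceiling(top_fraction * length(v))]
      norm >= cutoff
    } else {
      msk <- mask %||% array(TRUE, dim = dim)
      full <- array(NA_real_, dim = dim)
      full[which(as.vector(msk))] <- v
      bin <- postprocess_map(full, top_fraction = top_fraction,
                             min_cluster = min_cluster,
                             connectivity = connectivity, mask = msk)
      as.vector(bin)[which(as.vector(msk))]
    }
  }))
}

#' Stability, dwell time and fractional occupancy of coactivation patterns
#'
#' Repeats CAP clustering on `n_it` random subsamples (`fraction` of the
#' frames, drawn without replacement) and quantifies:
#' \itemize{
#'   \item \emph{stability}: CAPs of every iteration are matched to the
#'     first iteration ([match_caps()]), binarised
#'     ([postprocess_caps()]), and the Jaccard similarity
#'     \eqn{|A \cap B| / |A \cup B|} computed for each CAP across all
#'     \eqn{n_{it}(n_{it}-1)/2} iteration pairs;
#'   \item \emph{dwell time}: the number of frames assigned to each CAP at
#'     each iteration;
#'   \item \emph{percentage fractional occupancy}:
#'     \eqn{PFO_c = \frac{100}{N \, n_{it}} \sum_i n_c^i}, with N the total
#'     number of frames.
#' }
#'
#' @inheritParams kmeans_cosine
#' @param k Number of CAPs.
#' @param fraction Subsample fraction in (0, 1] (default 0.7).
#' @param n_it Number of iterations (default 25).
#' @param top_fraction,min_cluster,connectivity Binarisation parameters,
#'   see [postprocess_caps()].
#' @return An object of class `cap_stability`: tibbles `jaccard`
#'   (cap, iter_a, iter_b, jaccard), `dwell` (cap, iteration, frames),
#'   `pfo` (cap, pfo), plus `params` and the reference `cap_set`.
#' @export
cap_stability <- function(frames, k, fraction = 0.7, n_it = 25L, seed = 1L,
                          n_restarts = 5L, top_fraction = 0.2,
                          min_cluster = 16L, connectivity = 26L) {
  x <- frame_data(frames)
  check_scalar(fraction, "fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(n_it, "n_it", lower = 2, integerish = TRUE)
  n <- nrow(x)
  m <- max(round(fraction * n), k)
  dims <- if (inherits(frames, "frame_matrix")) frames$dim
  msk <- if (inherits(frames, "frame_matrix")) frames$mask
  iters <- purrr::map(seq_len(n_it), function(i) {
    idx <- withr::with_seed(child_seed(seed, 2000L + i),
                            sample.int(n, m, replace = FALSE))
    cs <- kmeans_cosine(x[idx, , drop = FALSE], k,
                        seed = child_seed(seed, 3000L + i),
                        n_restarts = n_restarts)
    cs
  })
  ref <- iters[[1]]
  aligned <- purrr::map(iters, function(cs) {
    mp <- match_caps(ref, cs)
    ord <- mp$other[order(mp$reference)]
    list(centroids = cs$centroids[ord, , drop = FALSE],
         sizes = cs$sizes[ord])
  })
  binary <- purrr::map(aligned, function(al) {
    postprocess_caps(al$centroids, top_fraction = top_fraction,
                     min_cluster = min_cluster, connectivity = connectivity,
                     dim = dims, mask = msk)
  })
  pairs <- utils::combn(n_it, 2)
  jac <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    jj <- purrr::map_dbl(seq_len(k), function(c) {
      jaccard_similarity(binary[[i]][c, ], binary[[j]][c, ])
    })
    tibble::tibble(cap = seq_len(k), iter_a = i, iter_b = j, jaccard = jj)
  })
  dwell <- purrr::imap_dfr(aligned, function(al, i) {
    tibble::tibble(cap = seq_len(k), iteration = i, frames = al$sizes)
  })
  pfo <- dwell |>
    dplyr::group_by(.data$cap) |>
    dplyr::summarise(pfo = 100 * sum(.data$frames) / (n * n_it),
                     .groups = "drop")
  structure(list(jaccard = dplyr::arrange(jac, .data$cap, .data$iter_a,
                                          .data$iter_b),
                 dwell = dwell, pfo = pfo,
                 params = list(k = k, fraction = fraction, n_it = n_it,
                               n_frames = n, subsample = m, seed = seed),
                 reference = ref),
            class = "cap_stability")
}

#' @export
print.cap_stability <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<cap_stability> K = %d, %d iterations of %d/%d frames\n  mean Jaccard %.3f; total PFO %.1f%%\n",
    p$k, p$n_it, p$subsample, p$n_frames, mean(x$jaccard$jaccard),
    sum(x$pfo$pfo)))
  invisible(x)
}

#' Jaccard similarity of two binary maps
#'
#' \eqn{|A \cap B| / |A \cup B|}; two empty maps have similarity 1.
#'
#' @param a,b Logical (or 0/1) vectors or arrays of equal length.
#' @return A number in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}
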