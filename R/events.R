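#' Zero-frequency resonator filter
#'
#' Passes a BOLD time course through an ideal zero-frequency resonator, a
#' second-order all-pole system with both poles at zero frequency
#' (transfer function \eqn{1 / (1 - 2 z^{-1} + z^{-2})}), realised as the
#' recursion \eqn{y_n = 2 y_{n-1} - y_{n-2} + m_n} with zero initial
#' conditions. The output grows polynomially with time; deviations from that
#' smooth trend carry the timing of transient BOLD events and are exposed by
#' [remove_local_mean()].
#'
#' One cascade is equivalent to two successive cumulative sums of the input.
#'
#' @param x Numeric time course \eqn{m_n}.
#' @param n_cascades Number of resonator passes (default 1).
#' @return Numeric vector, same length as `x`.
#' @seealso [detect_onsets()] for the full onset detector.
#' @examples
#' zfr_filter(c(1, 0, 0, 0, 0)) # unit ramp 1..5
#' @export
zfr_filter <- function(x, n_cascades = 1L) {
  check_numeric_series(x, "x")
  check_scalar(n_cascades, "n_cascades", lower = 1, integerish = TRUE)
  y <- x
  for (i in seq_len(n_cascades)) {
    y <- as.numeric(stats::filter(y, c(2, -1), method = "recursive"))
  }
  y
}

#' Remove the local mean from a resonator output
#'
#' Subtracts a moving average of half-width \eqn{N_1} from the resonated
#' signal: \eqn{z_n = y_n - \frac{1}{2N_1+1}\sum_{k=-N_1}^{N_1} y_{n-k}},
#' where `wz` \eqn{= 2N_1 + 1}. This removes the slowly growing polynomial
#' trend of the resonator so that event-related deviations oscillate around
#' zero. At the series edges the window is truncated to the available samples
#' and the mean taken over those.
#'
#' @param y Numeric vector, typically the output of [zfr_filter()].
#' @param wz Odd window length in samples (default 9).
#' @return Detrended numeric vector \eqn{z_n}, same length as `y`.
#' @export
remove_local_mean <- function(y, wz = 9L) {
  check_numeric_series(y, "y")
  check_scalar(wz, "wz", lower = 3, integerish = TRUE)
  if (wz %% 2 == 0) abort("`wz` must be odd.")
  n <- length(y)
  if (wz > n) abort("`wz` must not exceed the series length.")
  n1 <- (wz - 1L) / 2L
  # cumulative sum gives O(n) truncated-window means
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - n1, 1L)
  hi <- pmin(seq_len(n) + n1, n)
  y - (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Positive zero crossings of a detrended series
#'
#' Returns the indices at which the signal swings from negative to
#' non-negative, i.e. all `n >= 2` with `z[n-1] < 0` and `z[n] >= 0`.
#' Exact zeros count as non-negative; no crossing is reported at the first
#' sample. In the ZFR pipeline these crossings mark BOLD event onsets.
#'
#' @param z Numeric vector.
#' @return Integer vector of crossing indices (1-based), strictly increasing.
#' @export
positive_zero_crossings <- function(z) {
  check_numeric_series(z, "z", min_len = 2L)
  n <- length(z)
  idx <- which(z[-n] < 0 & z[-1L] >= 0) + 1L
  as.integer(idx)
}

#' Detect spontaneous BOLD event onsets in a time course
#'
#' Two detectors over one interface. `method = "zfr"` composes
#' [zfr_filter()], [remove_local_mean()] and [positive_zero_crossings()]:
#' the resonator emphasises the near-DC trend, local-mean removal exposes
#' transients, and positive zero crossings time-stamp event onsets.
#' `method = "threshold"` is the classical point-process baseline: the series
#' is z-scored and upward crossings of `threshold_sd` are reported
#' (`x[n-1] < theta <= x[n]`); with `all_points = TRUE` every supra-threshold
#' sample is returned instead (the literal point process).
#'
#' For the ZFR detector, crossings within \eqn{N_1 = (wz-1)/2} samples of
#' either edge are discarded: the truncated local-mean window is biased
#' against the resonator's polynomial trend there and produces boundary
#' artifacts unrelated to events.
#'
#' The resonator-plus-trend-removal cascade has negative passband gain at
#' the frequencies of interest (for band-limited input,
#' \eqn{z_n \approx -c\, m_n} with c > 0), so a positive BOLD transient
#' appears sign-inverted at the filter output. With
#' `zero_crossing = "corrected"` (default) onsets are the positive zero
#' crossings of the polarity-corrected output \eqn{-z_n}, which coincide
#' with the rise of the transient; `"literal"` uses \eqn{z_n} itself, whose
#' positive crossings trail the excursion by its duration. Exact zeros
#' (within `1e-9` of the signal's peak magnitude) are snapped to zero first
#' so that flat noiseless stretches cannot generate crossings from
#' floating-point dust. Detection presumes a zero-centred, band-limited
#' series; apply [bandpass()] first on raw data.
#'
#' @param x Numeric time course.
#' @param method `"zfr"` (default) or `"threshold"`.
#' @param wz Odd local-mean window length in samples for the ZFR (default 9).
#' @param n_cascades Resonator passes (default 1).
#' @param threshold_sd Threshold in standard-deviation units for the baseline
#'   detector (default 1).
#' @param all_points If `TRUE` (threshold method only), return every index
#'   above the threshold rather than upward crossings.
#' @param edge_guard If `TRUE` (default), drop ZFR crossings within
#'   \eqn{N_1} samples of the series edges.
#' @param zero_crossing `"corrected"` (default) marks onsets at positive
#'   zero crossings of the polarity-corrected output; `"literal"` uses the
#'   raw filter output.
#' @return Integer vector of onset indices (1-based), strictly increasing.
#' @examples
#' fix <- sim_event_series(c(21, 61, 101), n_time = 150, tr = 2, noise_sd = 0)
#' detect_onsets(bandpass(fix$series, tr = 2))
#' @export
detect_onsets <- function(x, method = c("zfr", "threshold"), wz = 9L,
                          n_cascades = 1L, threshold_sd = 1,
                          all_points = FALSE, edge_guard = TRUE,
                          zero_crossing = c("corrected", "literal")) {
  method <- match.arg(method)
  check_numeric_series(x, "x", min_len = 2L)
  if (method == "zfr") {
    check_flag(edge_guard, "edge_guard")
    zero_crossing <- match.arg(zero_crossing)
    z <- remove_local_mean(zfr_filter(x, n_cascades = n_cascades), wz = wz)
    if (zero_crossing == "corrected") z <- -z
    z[abs(z) <= 1e-9 * max(abs(z))] <- 0
    onsets <- positive_zero_crossings(z)
    if (edge_guard) {
      n1 <- (wz - 1L) / 2L
      onsets <- onsets[onsets > n1 & onsets <= length(x) - n1]
    }
    onsets
  } else {
    check_scalar(threshold_sd, "threshold_sd")
    check_flag(all_points, "all_points")
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      abort("`x` has zero variance; the threshold detector is undefined.")
    }
    z <- (x - mean(x)) / s
    if (all_points) {
      as.integer(which(z >= threshold_sd))
    } else {
      n <- length(z)
      as.integer(which(z[-n] < threshold_sd & z[-1L] >= threshold_sd) + 1L)
    }
  }
}

#' High-SNR segments around detected onsets
#'
#' The samples around a detected BOLD event carry most of the event's energy
#' and are treated as a high signal-to-noise (HSNR) window. For an onset at
#' index \eqn{l_o} the window starts one sample before the onset,
#' `max(l_o - 1, 1)`, and spans `w` samples, clipped at the end of the
#' series; windows left with fewer than 3 samples after clipping are dropped.
#' Overlapping windows are kept as-is (the segment-wise correlation of
#' [hsnr_correlation()] averages over them); their union is what frame
#' selection uses.
#'
#' @param onsets Integer onset indices (1-based), e.g. from [detect_onsets()].
#' @param w Window length in samples (default 6, about one HRF FWHM at
#'   TR = 2 s).
#' @param n_time Series length, used for clipping.
#' @param inclusive If `TRUE`, use the wider reading of the window as the
#'   index range \eqn{l_o - 1, \ldots, l_o + w - 1} (`w + 1` samples).
#' @return A tibble with columns `onset`, `start`, `length`.
#' @export
hsnr_segments <- function(onsets, w = 6L, n_time, inclusive = FALSE) {
  check_scalar(w, "w", lower = 2, integerish = TRUE)
  check_scalar(n_time, "n_time", lower = 3, integerish = TRUE)
  check_flag(inclusive, "inclusive")
  if (length(onsets) == 0) {
    return(tibble::tibble(onset = integer(), start = integer(),
                          length = integer()))
  }
  onsets <- as.integer(sort(unique(onsets)))
  if (any(onsets < 1L) || any(onsets > n_time)) {
    abort("`onsets` must lie within [1, n_time].")
  }
  len <- if (inclusive) w + 1L else w
  start <- pmax(onsets - 1L, 1L)
  length_clipped <- pmin(start + len - 1L, n_time) - start + 1L
  keep <- length_clipped >= 3L
  tibble::tibble(onset = onsets[keep], start = start[keep],
                 length = as.integer(length_clipped[keep]))
}

#' Recall and precision of recovered onsets
#'
#' Greedily matches detected onsets to ground-truth onsets (earliest truth
#' first, nearest unmatched detection within `tol` samples) and reports
#' recall (matched truths / truths) and precision (matched detections /
#' detections).
#'
#' @param truth,detected Integer onset index vectors.
#' @param tol Maximum |detected - truth| for a match, in samples
#'   (default 2).
#' @return A tibble with `recall`, `precision`, `n_matched`, `n_true`,
#'   `n_detected`.
#' @export
onset_recovery <- function(truth, detected, tol = 2L) {
  check_scalar(tol, "tol", lower = 0)
  truth <- sort(as.integer(truth))
  detected <- sort(as.integer(detected))
  free <- rep(TRUE, length(detected))
  matched <- 0L
  for (t in truth) {
    cand <- which(free & abs(detected - t) <= tol)
    if (length(cand) > 0) {
      best <- cand[which.min(abs(detected[cand] - t))]
      free[best] <- FALSE
      matched <- matched + 1L
    }
  }
  tibble::tibble(
    recall = if (length(truth) == 0) NA_real_ else matched / length(truth),
    precision = if (length(detected) == 0) NA_real_ else
      matched / length(detected),
    n_matched = matched, n_true = length(truth),
    n_detected = length(detected))
}

# Band-pass every row of a voxels x time matrix.
bandpass_rows <- function(mat, tr, low = 0.01, high = 0.1) {
  t(apply(mat, 1, bandpass, tr = tr, low = low, high = high))
}

# Union of segment time points as a sorted integer vector.
segment_union <- function(segments) {
  if (nrow(segments) == 0) return(integer())
  sort(unique(unlist(purrr::map2(segments$start, segments$length,
                                 ~ seq.int(.x, .x + .y - 1L)))))
}

#' Zero-phase band-pass filter for BOLD time courses
#'
#' Butterworth band-pass (order 4, applied forward and backward with
#' `signal::filtfilt()` for zero phase) with the conventional resting-state
#' band 0.01-0.1 Hz as default. Reduces scanner drift below the band and
#' high-frequency physiological noise above it.
#'
#' @param x Numeric time course.
#' @param tr Repetition time in seconds (sampling interval).
#' @param low,high Band edges in Hz; must satisfy
#'   `0 < low < high < 1/(2 tr)`.
#' @return Filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, tr, low = 0.01, high = 0.1) {
  check_numeric_series(x, "x", min_len = 12L)
  check_scalar(tr, "tr", lower = 0, strict_lower = TRUE)
  nyq <- 1 / (2 * tr)
  if (!(low > 0 && low < high && high < nyq)) {
    abort("Band edges must satisfy 0 < low < high < Nyquist = 1/(2 tr).")
  }
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  # the DC component is outside the passband; removing it before filtering
  # avoids forward-backward edge transients proportional to the baseline
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}
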