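#' Canonical double-gamma haemodynamic response function
#'
#' Samples the canonical double-gamma HRF at the repetition time: a gamma
#' density peaking around 5 s minus a scaled gamma undershoot peaking around
#' 15 s, normalised to unit peak. This is the kernel that turns a neural
#' event train into a BOLD component time course.
#'
#' @param tr Sampling interval in seconds (> 0).
#' @param duration Kernel length in seconds (default 32).
#' @param peak_delay,peak_disp Shape and dispersion of the response gamma
#'   (defaults 6 and 1; peak at `(peak_delay - 1) * peak_disp` = 5 s).
#' @param under_delay,under_disp Shape and dispersion of the undershoot gamma
#'   (defaults 16 and 1).
#' @param under_ratio Response-to-undershoot amplitude ratio (default 6).
#' @return Numeric kernel sampled at `0, tr, 2 tr, ...`, max value 1.
#' @examples
#' h <- hrf_kernel(tr = 2)
#' (which.max(h) - 1) * 2 # peak time in seconds
#' @export
hrf_kernel <- function(tr, duration = 32, peak_delay = 6, peak_disp = 1,
                       under_delay = 16, under_disp = 1, under_ratio = 6) {
  check_scalar(tr, "tr", lower = 0, strict_lower = TRUE)
  check_scalar(duration, "duration", lower = tr)
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = peak_delay, scale = peak_disp) -
    stats::dgamma(t, shape = under_delay, scale = under_disp) / under_ratio
  h / max(h)
}

# Convolve an event/impulse train with a kernel, truncated to the train length.
convolve_hrf <- function(train, kernel) {
  n <- length(train)
  full <- stats::convolve(train, rev(kernel), type = "open")
  full[seq_len(n)]
}
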