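test_that("zfr_filter matches the double-cumulative-sum oracle exactly", {
  expect_identical(zfr_filter(c(1, 0, 0, 0, 0)), c(1, 2, 3, 4, 5))
  expect_identical(zfr_filter(rep(0, 4)), rep(0, 4))
  expect_identical(zfr_filter(rep(1, 5)), c(1, 3, 6, 10, 15))
  withr::with_seed(11, {
    for (i in 1:50) {
      x <- as.numeric(sample(-50:50, sample(1:1000, 1), replace = TRUE))
      expect_identical(zfr_filter(x), cumsum(cumsum(x)))
      expect_identical(zfr_filter(x, n_cascades = 2),
                       cumsum(cumsum(cumsum(cumsum(x)))))
    }
  })
  expect_error(zfr_filter(c(1, NA, 2)), "non-finite")
})

test_that("remove_local_mean handles constants, ramps and hand-computed cases", {
  expect_equal(remove_local_mean(rep(7, 20), 5), rep(0, 20))
  # symmetric-window mean of a line equals its centre at interior points
  z <- remove_local_mean(as.numeric(0:19), 5)
  expect_equal(z[3:18], rep(0, 16))
  expect_equal(remove_local_mean(c(0, 0, 10, 0, 0), 3),
               c(0, -10 / 3, 20 / 3, -10 / 3, 0))
  expect_error(remove_local_mean(1:10, 4), "odd")
  expect_error(remove_local_mean(1:5, 7), "length")
})

test_that("positive zero crossings follow the sign-swing definition", {
  # spec cases are stated with 0-based indices; R indices are 1-based
  expect_identical(positive_zero_crossings(c(-1, -0.5, 0.2, 0.8, -0.3, 0.4)),
                   c(3L, 6L))
  expect_identical(positive_zero_crossings(c(1, 2, 3)), integer())
  # an exact zero belongs to the non-negative side
  expect_identical(positive_zero_crossings(c(-1, 0, -1, 1)), c(2L, 4L))
})

test_that("ZFR detector recovers noiseless planted onsets within 2 TR", {
  fix <- sim_event_series(21L, n_time = 150, tr = 2, noise_sd = 0)
  on <- detect_onsets(bandpass(fix$series, tr = 2))
  hits <- on[abs(on - 21) <= 2]
  expect_length(hits, 1)
  fix3 <- sim_event_series(c(21, 61, 101), n_time = 150, tr = 2,
                           noise_sd = 0)
  on3 <- detect_onsets(bandpass(fix3$series, tr = 2))
  for (t in fix3$onsets) expect_true(any(abs(on3 - t) <= 2))
  expect_length(detect_onsets(rep(3, 150)), 0)
})

test_that("ZFR detection is amplitude-scale invariant and shift covariant", {
  fix <- sim_event_series(c(31, 71, 111), n_time = 160, tr = 2, noise_sd = 0)
  x <- bandpass(fix$series, tr = 2)
  base <- detect_onsets(x)
  for (c in c(0.01, 3, 1e4)) {
    expect_identical(detect_onsets(c * x), base)
  }
  # delaying the event train shifts interior recovered onsets by the delay
  d <- 6L
  fixd <- sim_event_series(c(31, 71, 111) + d, n_time = 160, tr = 2,
                           noise_sd = 0)
  shifted <- detect_onsets(bandpass(fixd$series, tr = 2))
  near <- function(ons, t) ons[abs(ons - t) <= 2] - t
  for (t in fix$onsets) {
    expect_equal(near(shifted, t + d), near(base, t))
  }
})

test_that("onset recovery on seeded fixtures stays at its measured level", {
  # noiseless: every planted onset recovered within 2 TR
  fixes <- make_recovery_fixtures(50, noise_sd = 0)
  rec <- vapply(fixes, function(f) {
    onset_recovery(f$onsets,
                   detect_onsets(bandpass(f$series, tr = f$tr)))$recall
  }, numeric(1))
  expect_equal(mean(rec), 1)
  # regression level at matched noise (sd = peak amplitude)
  fixes_n <- make_recovery_fixtures(50, noise_sd = 1, master_seed = 7L)
  perf <- do.call(rbind, lapply(fixes_n, function(f) {
    r <- onset_recovery(f$onsets,
                        detect_onsets(bandpass(f$series, tr = f$tr)))
    c(r$recall, r$precision)
  }))
  expect_gte(mean(perf[, 1]), 0.6)
  expect_gte(mean(perf[, 2]), 0.2)
})

test_that("threshold detector reports crossings or all supra-threshold points", {
  x <- c(-1, 2, -1, 2, -1)
  z <- (x - mean(x)) / sd(x)
  expect_identical(detect_onsets(x, method = "threshold"),
                   which(c(FALSE, z[-1] >= 1 & z[-5] < 1)))
  expect_identical(detect_onsets(x, method = "threshold", all_points = TRUE),
                   which(z >= 1))
  expect_length(detect_onsets(c(0.1, 0.2, 0.1, 0.2), method = "threshold",
                              threshold_sd = 5), 0)
  expect_error(detect_onsets(rep(1, 10), method = "threshold"),
               "zero variance")
})

test_that("ZFR extracts fewer onsets than the literal point process", {
  # data-reduction direction: ~12 vs ~25 onsets per 150-sample course
  fixes <- make_recovery_fixtures(30, noise_sd = 1, master_seed = 99L)
  counts <- vapply(fixes, function(f) {
    x <- bandpass(f$series, tr = f$tr)
    c(zfr = length(detect_onsets(x)),
      thr = length(detect_onsets(x, method = "threshold",
                                 all_points = TRUE)))
  }, numeric(2))
  expect_lt(mean(counts["zfr", ]), mean(counts["thr", ]))
})

test_that("HSNR windows start one sample before the onset and clip at edges", {
  s <- hsnr_segments(11L, w = 6, n_time = 100)
  expect_equal(s$start, 10L)
  expect_equal(s$length, 6L)
  # left edge: onset at the first sample
  s0 <- hsnr_segments(1L, w = 6, n_time = 100)
  expect_equal(unlist(s0[1, c("start", "length")], use.names = FALSE),
               c(1L, 6L))
  # right edge: clipped to >= 3 samples or dropped
  s99 <- hsnr_segments(99L, w = 6, n_time = 100)
  expect_equal(unlist(s99[1, c("start", "length")], use.names = FALSE),
               c(98L, 3L))
  expect_equal(nrow(hsnr_segments(100L, w = 6, n_time = 100)), 0)
  # literal wider reading spans w + 1 samples
  si <- hsnr_segments(11L, w = 6, n_time = 100, inclusive = TRUE)
  expect_equal(si$length, 7L)
  expect_error(hsnr_segments(500L, w = 6, n_time = 100), "within")
})

test_that("band-pass keeps the passband and rejects out-of-band energy", {
  t <- seq(0, by = 2, length.out = 400)
  amp_at <- function(y, f) {
    fit <- lm(y ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  inband <- sin(2 * pi * 0.05 * t)
  expect_gte(amp_at(bandpass(inband, tr = 2), 0.05), 0.9)
  outband <- sin(2 * pi * 0.2 * t)
  expect_lte(amp_at(bandpass(outband, tr = 2), 0.2), 0.1)
  expect_equal(bandpass(rep(0, 100), tr = 2), rep(0, 100))
  expect_error(bandpass(rnorm(100), tr = 2, low = 0.2, high = 0.1), "Band")
})
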