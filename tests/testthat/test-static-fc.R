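test_that("conditional rate matches identities and the exhaustive oracle", {
  expect_equal(conditional_rate(c(3, 10, 20), c(3, 10, 20)), 1)
  expect_equal(conditional_rate(c(3, 10, 20), integer()), 0)
  expect_equal(conditional_rate(c(3, 10, 20), c(3, 11, 40)), 2 / 3)
  expect_equal(cr_oracle(c(3, 10, 20), c(3, 11, 40)), 2 / 3)
  expect_error(conditional_rate(integer(), c(1, 2)), "empty seed")
  # greedy smallest-shift-first matching is bounded by the exhaustive
  # maximum matching and stays in [0, 1]
  withr::with_seed(21, {
    for (i in 1:60) {
      a <- sort(sample(1:60, sample(2:8, 1)))
      b <- sort(sample(1:60, sample(0:8, 1)))
      cr <- conditional_rate(a, b)
      expect_true(cr >= 0 && cr <= 1)
      expect_lte(cr, cr_oracle(a, b))
    }
  })
})

test_that("conditional rate is monotone in max_shift and symmetric at shift 0", {
  withr::with_seed(31, {
    for (i in 1:30) {
      a <- sort(sample(1:80, 6))
      b <- sort(sample(1:80, 8))
      crs <- vapply(0:4, function(s) conditional_rate(a, b, max_shift = s),
                    numeric(1))
      expect_true(all(diff(crs) >= 0))
      # matched pairs at shift 0 are symmetric
      expect_equal(conditional_rate(a, b, max_shift = 0) * length(a),
                   conditional_rate(b, a, max_shift = 0) * length(b))
    }
  })
  # the literal (non-unique) sum can exceed 1
  expect_gt(conditional_rate(c(5), c(5, 6, 7), unique_matching = FALSE), 1)
})

test_that("HSNR correlation equals Pearson in the degenerate full window", {
  withr::local_seed(77)
  x <- cumsum(rnorm(50, 0, 1))
  segs <- hsnr_segments(11L, w = 6, n_time = 50)
  expect_equal(hsnr_correlation(x, x, segs), 1)
  expect_equal(hsnr_correlation(x, -x, segs), -1)
  one <- tibble::tibble(onset = 1L, start = 1L, length = 6L)
  expect_equal(hsnr_correlation(1:6 + 0, 2 * (1:6) + 3, one), 1)
  full <- tibble::tibble(onset = 1L, start = 1L, length = 50L)
  y <- rnorm(50)
  expect_equal(hsnr_correlation(x, y, full), cor(x, y), tolerance = 1e-12)
  expect_error(hsnr_correlation(x, y, hsnr_segments(integer(), 6, 50)),
               "empty")
  flat <- tibble::tibble(onset = 1L, start = 1L, length = 10L)
  expect_error(hsnr_correlation(rep(1, 20), y[1:20], flat), "degenerate")
})

test_that("fc_map self-connectivity is exact for every metric", {
  ds <- small_sim(seed = 13, n_subjects = 1)
  sub <- ds$subjects[[1]]
  ctr <- round(t(zfrfc:::component_centers(c(40L, 40L), 6))[, 1])
  seedvox <- as.integer(c(ctr[1], ctr[2]))
  for (metric in c("correlation", "cr_zfr", "cr_threshold", "hsnr")) {
    m <- fc_map(sub$data, seedvox, metric = metric)
    flat <- seedvox[1] + (seedvox[2] - 1) * 40
    idx <- match(flat, which(as.vector(m$mask)))
    expect_equal(m$values[idx], 1, tolerance = 1e-10)
  }
})

test_that("fc_map separates planted components from the rest", {
  ds <- small_sim(seed = 13, n_subjects = 1)
  sub <- ds$subjects[[1]]
  mask1 <- which(as.vector(component_mask(sub$spatial, 1)))
  mask2 <- which(as.vector(component_mask(sub$spatial, 2)))
  seed_tc <- colMeans(matrix(sub$data, 1600, 150)[mask1, ])
  for (metric in c("correlation", "cr_zfr", "hsnr")) {
    m <- fc_map(sub$data, seed_tc, metric = metric)
    expect_gt(mean(m$values[mask1], na.rm = TRUE),
              mean(m$values[mask2], na.rm = TRUE))
  }
})

test_that("CR of white-noise voxels is centred at the permutation chance rate", {
  withr::with_seed(17, {
    arr <- array(rnorm(20 * 20 * 150), dim = c(20, 20, 150))
    seed_tc <- rnorm(150)
    m <- fc_map(arr, seed_tc, metric = "cr_zfr")
    # chance rate: CR against onset trains shuffled uniformly in time
    seed_on <- detect_onsets(bandpass(seed_tc, tr = 2))
    perm <- replicate(500, {
      k <- length(detect_onsets(bandpass(rnorm(150), tr = 2)))
      conditional_rate(seed_on, sort(sample(150, max(k, 1))))
    })
    expect_lt(abs(mean(m$values) - mean(perm)), 0.05)
  })
})

test_that("map post-processing keeps the top fraction and large clusters", {
  toy <- array(1:100 + 0, dim = c(10, 10))
  bin <- postprocess_map(toy, top_fraction = 0.2, min_cluster = 1)
  expect_identical(which(as.vector(bin)), 81:100)
  # near-total fraction keeps everything but the minimum
  bin99 <- postprocess_map(toy, top_fraction = 0.99, min_cluster = 1)
  expect_equal(sum(bin99), 99)
  # cluster-extent filter: 20-voxel blob survives, 10-voxel blob dropped
  m <- array(seq(0, 1, length.out = 900), dim = c(30, 30))
  m[2:5, 2:6] <- 10       # 20 voxels
  m[20:24, 20:21] <- 9    # 10 voxels
  b <- postprocess_map(m, top_fraction = 30 / 900, min_cluster = 16)
  expect_true(all(b[2:5, 2:6]))
  expect_false(any(b[20:24, 20:21]))
  expect_equal(sum(b), 20)
  # invariant to affine rescaling of the map
  expect_identical(postprocess_map(5 * m - 3, top_fraction = 30 / 900,
                                   min_cluster = 16), b)
  expect_error(postprocess_map(array(1, dim = c(5, 5))), "constant")
})

test_that("connected-component labelling respects the neighbourhood choice", {
  a <- array(FALSE, dim = c(5, 5))
  a[1, 1] <- TRUE
  a[2, 2] <- TRUE  # diagonal contact only
  lab8 <- zfrfc:::label_components(a, connectivity = 26)
  expect_equal(lab8[1, 1], lab8[2, 2])
  lab4 <- zfrfc:::label_components(a, connectivity = 6)
  expect_true(lab4[1, 1] != lab4[2, 2])
})

test_that("ROI averaging reduces to the obvious cases", {
  arr <- array(0, dim = c(2, 2, 10))
  x <- rnorm(10)
  arr[1, 1, ] <- x
  arr[2, 1, ] <- -x
  arr[1, 2, ] <- 5
  labels <- array(c(1L, 1L, 2L, 0L), dim = c(2, 2))
  tc <- roi_timecourses(arr, labels)
  expect_equal(tc[, "1"], rep(0, 10))
  expect_equal(tc[, "2"], rep(5, 10))
  one <- roi_timecourses(arr, array(c(0L, 0L, 3L, 0L), dim = c(2, 2)))
  expect_equal(one[, "3"], rep(5, 10))
  expect_error(roi_timecourses(arr, array(0L, dim = c(2, 2))), "foreground")
})
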