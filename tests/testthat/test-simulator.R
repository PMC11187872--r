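test_that("event trains follow the per-type Bernoulli model", {
  cfg0 <- sim_config(event_probs = rep(0, 4), rng_seed = 1)
  expect_equal(sim_event_train(cfg0, 1)$train, rep(0L, 150))
  cfg1 <- sim_config(event_probs = c(1, 0, 0, 0), rng_seed = 1)
  expect_equal(sim_event_train(cfg1, 1)$train, rep(1L, 150))
  # empirical count within 3 binomial standard deviations of n * p
  cfg <- sim_config(n_time = 10000L, event_probs = c(0.06, 0, 0, 0),
                    rng_seed = 3)
  tr <- sim_event_train(cfg, 1)
  expect_lt(abs(sum(tr$train) - 600), 3 * sqrt(10000 * 0.06 * 0.94))
  expect_error(sim_config(event_probs = c(0.5, 1.2, 0, 0)), "probabilities")
})

test_that("the HRF kernel peaks at 4-6 s and convolution is linear", {
  h <- hrf_kernel(tr = 2)
  expect_equal(max(h), 1)
  peak_t <- (which.max(h) - 1) * 2
  expect_true(peak_t >= 4 && peak_t <= 6)
  # grid refinement: peak time converges to the continuous 5 s peak
  h_fine <- hrf_kernel(tr = 0.01)
  expect_equal((which.max(h_fine) - 1) * 0.01, 5, tolerance = 0.02)
  expect_error(hrf_kernel(tr = 0), "tr")
  # scaling the kernel scales the convolution output
  train <- rep(0, 60); train[c(10, 30)] <- 1
  expect_equal(zfrfc:::convolve_hrf(train, 3 * h),
               3 * zfrfc:::convolve_hrf(train, h))
})

test_that("1D event fixtures are sums of shifted kernels", {
  z <- sim_event_series(integer(), n_time = 80, tr = 2, noise_sd = 0)
  expect_equal(z$series, rep(0, 80))
  h <- hrf_kernel(2)
  one <- sim_event_series(21L, n_time = 80, tr = 2, noise_sd = 0)
  expected <- rep(0, 80)
  expected[21:(20 + length(h))] <- h
  expect_equal(one$series, expected)
  three <- sim_event_series(c(11, 41, 61), n_time = 120, tr = 2,
                            noise_sd = 0)
  by_hand <- Reduce(`+`, lapply(c(11, 41, 61), function(o) {
    s <- rep(0, 120)
    s[o:(o + length(h) - 1)] <- h
    s
  }))
  expect_equal(three$series, by_hand)
  expect_error(sim_event_series(300L, n_time = 100), "within")
})

test_that("the generator is deterministic and linear in component amplitude", {
  cfg <- sim_config(n_subjects = 2, grid = c(30, 30), blob_sigma = 3,
                    rng_seed = 42)
  a <- sim_dataset(cfg)
  b <- sim_dataset(cfg)
  expect_identical(a$subjects[[1]]$data, b$subjects[[1]]$data)
  expect_identical(a$subjects[[2]]$events, b$subjects[[2]]$events)
  # doubling event amplitudes doubles the noise-free signal deviation
  cfg2 <- sim_config(n_subjects = 2, grid = c(30, 30), blob_sigma = 3,
                     rng_seed = 42, event_amps = 2 * c(1, 1.2, 1.2, 1.5))
  d <- sim_dataset(cfg2)
  base <- zfrfc:::baseline_field(cfg$grid)
  dev1 <- sweep(a$subjects[[1]]$noise_free, c(1, 2), base)
  dev2 <- sweep(d$subjects[[1]]$noise_free, c(1, 2), base)
  expect_equal(dev2, 2 * dev1, tolerance = 1e-12)
})

test_that("voxels inside a component track its time course when noise-free", {
  cfg <- sim_config(n_subjects = 1, grid = c(30, 30), blob_sigma = 3,
                    cnr_range = c(1e6, 1e6), rng_seed = 8)
  ds <- sim_dataset(cfg)
  sub <- ds$subjects[[1]]
  m <- component_mask(sub$spatial, 2)
  vm <- matrix(sub$data, 900, 150)
  rs <- apply(vm[which(as.vector(m)), ], 1, cor, y = sub$tc[, 2])
  expect_true(all(rs > 0.99))
})

test_that("Rician noise has the configured scale and limiting distributions", {
  # large signal: approximately Gaussian with sd sigma
  x <- rep(1000, 1e5)
  r <- zfrfc:::rician(x, 5, seed = 1)
  expect_equal(sd(r - x), 5, tolerance = 0.05)
  expect_lt(abs(mean(r - x)), 0.1)
  # zero signal: Rayleigh with mean sigma * sqrt(pi / 2)
  r0 <- zfrfc:::rician(rep(0, 1e5), 2, seed = 2)
  expect_equal(mean(r0), 2 * sqrt(pi / 2), tolerance = 0.02)
  expect_equal(sd(r0), 2 * sqrt(2 - pi / 2), tolerance = 0.02)
  # empirical sigma in a generated dataset matches peak / CNR within 5%
  cfg <- sim_config(n_subjects = 1, grid = c(40, 40), blob_sigma = 4,
                    cnr_range = c(0.4, 0.4), rng_seed = 3)
  ds <- sim_dataset(cfg)
  sub <- ds$subjects[[1]]
  peak <- max(abs(sweep(sub$noise_free, c(1, 2),
                        zfrfc:::baseline_field(cfg$grid))))
  expect_equal(sd(sub$data - sub$noise_free), peak / 0.4, tolerance = 0.05)
})

test_that("configuration rejects impossible layouts", {
  expect_error(sim_dataset(sim_config(grid = c(12, 12), blob_sigma = 6)),
               "too small")
  expect_error(sim_config(cnr_range = c(0, 1)), "cnr_range")
  expect_error(sim_config(n_time = 20), "HRF length")
})

test_that("noise-frame augmentation appends event-free frames", {
  ds <- small_sim(seed = 9)
  aug <- sim_augment_noise_frames(ds, fraction = 0.3)
  expect_length(aug, 2)
  expect_equal(dim(aug[[1]])[3], 150 + 45)
  expect_equal(attr(aug, "n_structured"), 150L)
  # original frames preserved verbatim
  expect_identical(aug[[1]][, , 1:150], ds$subjects[[1]]$data)
})
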