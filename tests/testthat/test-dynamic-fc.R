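test_that("frame selection counts and subset relations hold", {
  ds <- small_sim(seed = 23)
  all_fm <- select_frames(ds, mode = "all")
  expect_equal(nrow(all_fm$frames), 2 * 150)
  expect_equal(ncol(all_fm$frames), 1600)
  hz <- select_frames(ds, mode = "hsnr_zfr")
  expect_true(nrow(hz$frames) > 0)
  expect_true(nrow(hz$frames) <= nrow(all_fm$frames))
  # per subject, selected times are a subset of all times
  sel <- split(hz$provenance$time, hz$provenance$subject)
  for (s in names(sel)) expect_true(all(sel[[s]] %in% 1:150))
  # a detector that fires nowhere contributes no frames, with a warning
  flat <- list(array(rnorm(4 * 20, sd = 1e-12) + 7, dim = c(2, 2, 20)))
  expect_warning(
    try(select_frames(flat, mode = "hsnr_zfr", preprocess = FALSE,
                      quorum = 1), silent = TRUE),
    "no frames")
})

test_that("cosine k-means recovers separable patterns exactly", {
  pf <- planted_frames(k = 2, v = 100, n_per = 50)
  cs <- kmeans_cosine(pf$frames, 2, seed = 4)
  expect_equal(cs$distortion, 0, tolerance = 1e-12)
  agree <- max(mean(cs$labels == pf$truth), mean(cs$labels == 3 - pf$truth))
  expect_equal(agree, 1)
  # centroids align with the generating patterns
  mp <- match_caps(pf$patterns, cs)
  expect_true(all(mp$correlation > 0.999))
  # cosine distance ignores positive frame scaling
  scaled <- pf$frames * runif(nrow(pf$frames), 0.5, 5)
  cs2 <- kmeans_cosine(scaled, 2, seed = 4)
  expect_equal(cs2$labels, cs$labels)
  # determinism
  expect_identical(kmeans_cosine(pf$frames, 2, seed = 9)$labels,
                   kmeans_cosine(pf$frames, 2, seed = 9)$labels)
})

test_that("singleton clusters and zero-norm frames are handled", {
  withr::with_seed(5, {
    x <- matrix(rnorm(8 * 10), 8, 10)
  })
  cs <- kmeans_cosine(x, 8, seed = 1)
  expect_equal(cs$distortion, 0, tolerance = 1e-9)
  x0 <- rbind(x, 0)
  expect_warning(cs0 <- kmeans_cosine(x0, 3, seed = 1), "zero-norm")
  expect_true(is.na(cs0$labels[9]))
})

test_that("the elbow rule finds a planted knee; min-distortion takes the largest K", {
  k <- 2:10
  knee <- c(100, 60, 30, 5, 4.5, 4.2, 4, 3.9, 3.8)
  expect_equal(elbow_k(k, knee), 5)
  expect_equal(elbow_k(k, knee, rule = "min_distortion"), 10)
  # on clustered data the scanned distortion curve bends at the true K
  pf <- planted_frames(k = 6, v = 300, n_per = 40, noise_sd = 0.2, seed = 6)
  pick <- choose_k_elbow(pf$frames, k_range = 2:12, seed = 3,
                         n_restarts = 3)
  expect_true(pick$k %in% 5:7)
  expect_true(all(diff(pick$distortions$distortion) < 1e-6))
})

test_that("CAP matching recovers permutations and agrees with brute force", {
  withr::with_seed(41, {
    ref <- matrix(rnorm(5 * 60), 5, 60)
  })
  expect_equal(match_caps(ref, ref)$other, 1:5)
  perm <- c(3, 1, 5, 2, 4)
  mp <- match_caps(ref, ref[perm, ])
  expect_equal(mp$other[perm], 1:5)
  expect_true(all(mp$correlation > 0.999))
  # Hungarian solution equals exhaustive search on random costs
  withr::with_seed(42, {
    for (i in 1:25) {
      n <- sample(2:6, 1)
      cost <- matrix(rnorm(n * n), n)
      oracle <- assignment_oracle(cost)
      got <- zfrfc:::solve_assignment(cost)
      expect_equal(sum(cost[cbind(1:n, got)]), oracle$cost,
                   tolerance = 1e-12)
    }
  })
  expect_error(match_caps(ref, ref[1:3, ]), "same K")
})

test_that("CAP binarisation applies the top-fraction threshold per centroid", {
  cent <- rbind(1:100, 100:1) + 0
  bin <- postprocess_caps(cent, top_fraction = 0.2)
  expect_equal(which(bin[1, ]), 81:100)
  expect_equal(which(bin[2, ]), 1:20)
  # with a voxel grid the cluster-extent filter also applies
  m <- array(seq(0, 1, length.out = 900), dim = c(30, 30))
  m[2:5, 2:6] <- 10
  m[20:24, 20:21] <- 9
  b <- postprocess_caps(rbind(as.vector(m)), top_fraction = 30 / 900,
                        min_cluster = 16, dim = c(30L, 30L))
  expect_equal(sum(b), 20)
})

test_that("stability bookkeeping: Jaccard pairs, dwell sums and PFO identity", {
  pf <- planted_frames(k = 3, v = 120, n_per = 40)
  st <- cap_stability(pf$frames, 3, fraction = 0.7, n_it = 5, seed = 2,
                      n_restarts = 3)
  # noise-free separable frames reproduce identical CAPs each iteration
  expect_true(all(st$jaccard$jaccard == 1))
  expect_equal(nrow(st$jaccard), 3 * choose(5, 2))
  # per-iteration dwell adds up to the subsample size
  sums <- tapply(st$dwell$frames, st$dwell$iteration, sum)
  expect_true(all(sums == round(0.7 * 120)))
  # sum of PFO equals 100 * fraction when every CAP is retained
  expect_equal(sum(st$pfo$pfo), 100 * 0.7)
  expect_error(cap_stability(pf$frames, 3, fraction = 0), "fraction")
})

test_that("Jaccard similarity is a bounded symmetric overlap", {
  withr::with_seed(8, {
    for (i in 1:20) {
      a <- runif(50) > 0.5
      b <- runif(50) > 0.5
      j <- jaccard_similarity(a, b)
      expect_true(j >= 0 && j <= 1)
      expect_equal(j, jaccard_similarity(b, a))
      expect_equal(jaccard_similarity(a, a), 1)
    }
  })
  expect_equal(jaccard_similarity(logical(5), logical(5)), 1)
})

test_that("tidiers summarise CAP objects consistently", {
  pf <- planted_frames(k = 3, v = 120, n_per = 40)
  cs <- kmeans_cosine(pf$frames, 3, seed = 2)
  td <- tidy(cs)
  expect_equal(nrow(td), 3 * 120)
  gl <- glance(cs)
  expect_equal(gl$n_frames, 120)
  st <- cap_stability(pf$frames, 3, fraction = 0.7, n_it = 4, seed = 2,
                      n_restarts = 2)
  tst <- tidy(st)
  expect_equal(nrow(tst), 3)
  expect_equal(sum(tst$pfo), 100 * 0.7)
  expect_equal(glance(st)$mean_jaccard, mean(st$jaccard$jaccard))
})
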