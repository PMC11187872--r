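# Shared fixtures, built in code at test time.

# Seeded event-series fixtures: 3-6 events, >= 15 TR apart, T = 150, TR = 2.
make_recovery_fixtures <- function(n, noise_sd = 0, master_seed = 2024L) {
  withr::with_seed(master_seed, {
    lapply(seq_len(n), function(i) {
      n_ev <- sample(3:6, 1)
      repeat {
        ons <- sort(sample(10:140, n_ev))
        if (min(diff(ons)) >= 15) break
      }
      sim_event_series(ons, n_time = 150, tr = 2, noise_sd = noise_sd,
                       seed = master_seed + i)
    })
  })
}

# Small, fast simulated dataset used across module tests.
small_sim <- function(seed = 5L, n_subjects = 2L, cnr = c(1, 1)) {
  sim_dataset(sim_config(n_subjects = n_subjects, grid = c(40L, 40L),
                         blob_sigma = 4, cnr_range = cnr, rng_seed = seed))
}

# K orthogonal block patterns over V voxels, n_per noisy frames each.
planted_frames <- function(k = 6L, v = 600L, n_per = 100L, noise_sd = 0,
                           seed = 1L) {
  block <- v %/% k
  pats <- matrix(0, k, v)
  for (i in seq_len(k)) pats[i, ((i - 1) * block + 1):(i * block)] <- 1
  frames <- pats[rep(seq_len(k), each = n_per), , drop = FALSE]
  if (noise_sd > 0) {
    frames <- frames + withr::with_seed(seed, {
      matrix(rnorm(length(frames), 0, noise_sd), nrow(frames))
    })
  }
  list(patterns = pats, frames = frames,
       truth = rep(seq_len(k), each = n_per))
}

# Exhaustive maximum-matching oracle for the conditional rate: tries every
# injective assignment of seed onsets to target onsets within the shift
# window and returns the maximum number of matches.
cr_oracle <- function(seed_onsets, target_onsets, max_shift = 2L) {
  seed_onsets <- sort(seed_onsets)
  target_onsets <- sort(target_onsets)
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (length(seed_onsets) - i + 1) <= best) return()
    if (i > length(seed_onsets)) {
      best <<- max(best, count)
      return()
    }
    cand <- which(!used & target_onsets >= seed_onsets[i] &
                    target_onsets <= seed_onsets[i] + max_shift)
    for (j in cand) {
      used[j] <- TRUE
      recurse(i + 1L, used, count + 1L)
      used[j] <- FALSE
    }
    recurse(i + 1L, used, count)
  }
  recurse(1L, rep(FALSE, length(target_onsets)), 0L)
  best / length(seed_onsets)
}

# Brute-force optimal assignment (minimum cost) over all permutations.
assignment_oracle <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  ps <- perms(seq_len(n))
  costs <- vapply(ps, function(p) sum(cost[cbind(seq_len(n), p)]),
                  numeric(1))
  list(assignment = ps[[which.min(costs)]], cost = min(costs))
}
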