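# State covariances, Markov state sequences, and cohort generation.

test_that("block covariances have the prescribed entry structure", {
  covs <- make_state_covariances(4, n_states = 2, n_blocks = 2,
                                 within_r = 0.8, between_r = 0, seed = 1)
  for (m in covs) {
    expect_identical(dim(m), c(4L, 4L))
    expect_equal(m, t(m))
    expect_equal(diag(m), rep(1, 4))
    off <- m[upper.tri(m)]
    expect_true(all(vapply(off, function(v)
      isTRUE(all.equal(v, 0)) || isTRUE(all.equal(v, 0.8)), TRUE)))
  }
  expect_equal(make_state_covariances(5, 1, n_blocks = 2, within_r = 0,
                                      between_r = 0, seed = 1)[[1]],
               diag(5))
})

test_that("generated states are distinct, positive definite, deterministic", {
  covs <- make_state_covariances(40, 3, seed = 1)
  for (i in 1:2) for (j in (i + 1):3)
    expect_gt(norm(covs[[i]] - covs[[j]], "F"), 0)
  for (m in covs)
    expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_identical(covs, make_state_covariances(40, 3, seed = 1))
  expect_false(identical(covs, make_state_covariances(40, 3, seed = 2)))
})

test_that("positive-definite repair floors eigenvalues and restores unit diagonal", {
  m <- matrix(0.99, 4, 4); diag(m) <- 1
  m[1, 2] <- m[2, 1] <- -0.99   # makes the matrix indefinite
  r <- dfcpattern:::ensure_positive_definite(m, floor_frac = 1e-6)
  expect_gt(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(diag(r), rep(1, 4))
})

test_that("state sequences honour degenerate occupancy and dwell", {
  s1 <- state_spec(1, diag(3), occupancy = c(A = 1), mean_dwell = 5)
  expect_equal(sample_state_sequence(50, list(s1), "A", seed = 1), rep(1L, 50))
  two <- list(state_spec(1, diag(3), c(A = 1, B = 0.5), mean_dwell = 5),
              state_spec(2, diag(3), c(A = 0, B = 0.5), mean_dwell = 5))
  z <- sample_state_sequence(500, two, "A", seed = 3)
  expect_true(all(z == 1L))
  expect_error(sample_state_sequence(10, two, "C", seed = 1),
               "no occupancy")
})

test_that("empirical occupancy converges to the configured distribution", {
  two <- list(state_spec(1, diag(3), c(A = 0.5), mean_dwell = 2),
              state_spec(2, diag(3), c(A = 0.5), mean_dwell = 2))
  z <- sample_state_sequence(10000, two, "A", seed = 7)
  expect_lt(abs(mean(z == 1) - 0.5), 0.05)
  skew <- list(state_spec(1, diag(3), c(A = 0.8), mean_dwell = 4),
               state_spec(2, diag(3), c(A = 0.2), mean_dwell = 4))
  z2 <- sample_state_sequence(10000, skew, "A", seed = 11)
  expect_lt(abs(mean(z2 == 1) - 0.8), 0.05)
})

test_that("subject series reproduce the active state's covariance", {
  cfg <- cohort_config(n_subjects_per_group = 1, n_roi = 5,
                       tr_by_group = c(A = 3), n_timepoints_by_group = c(A = 5000L),
                       states = list(state_spec(1, diag(5), c(A = 1),
                                                mean_dwell = 10)),
                       observation_noise_sd = 0, seed = 1)
  ts <- generate_subject_timeseries(cfg, "A", subject_seed = 42)
  expect_identical(dim(ts$series), c(5L, 5000L))
  expect_lt(max(abs(cov(t(ts$series)) - diag(5))), 0.1)
  # determinism contract
  ts2 <- generate_subject_timeseries(cfg, "A", subject_seed = 42)
  expect_identical(ts$series, ts2$series)
  expect_false(identical(
    ts$series, generate_subject_timeseries(cfg, "A", 43)$series))
})

test_that("windowed correlations inside pure-state runs recover the state", {
  covs <- make_state_covariances(12, 2, n_blocks = 2, within_r = 0.8,
                                 between_r = 0, seed = 5)
  states <- list(state_spec(1, covs[[1]], c(A = 0.5), mean_dwell = 60),
                 state_spec(2, covs[[2]], c(A = 0.5), mean_dwell = 60))
  cfg <- cohort_config(n_subjects_per_group = 1, n_roi = 12,
                       tr_by_group = c(A = 3),
                       n_timepoints_by_group = c(A = 3000L),
                       states = states, observation_noise_sd = 0, seed = 1)
  ts <- generate_subject_timeseries(cfg, "A", subject_seed = 9)
  w <- 12
  runs <- rle(ts$state_seq)
  ends <- cumsum(runs$lengths)
  hits <- 0; tot <- 0
  for (r in which(runs$lengths >= w + 10)) {
    start <- ends[r] - runs$lengths[r] + 1
    win <- ts$series[, (start + 5):(start + 5 + w - 1)]
    rc <- suppressWarnings(cor(t(win)))
    own <- runs$values[r]
    d_own <- norm(rc - covs[[own]], "F")
    d_other <- norm(rc - covs[[3 - own]], "F")
    tot <- tot + 1
    if (d_own < d_other) hits <- hits + 1
  }
  expect_gte(tot, 10)
  expect_gte(hits / tot, 0.9)
})

test_that("cohorts carry correct manifest, truth, and roundtrip through disk", {
  co <- quick_cohort(n_per_group = 2, n_roi = 10, seed = 4)
  expect_equal(nrow(co$manifest), 4)
  expect_equal(co$manifest$tr[co$manifest$group == "A"], c(3, 3))
  expect_equal(co$manifest$tr[co$manifest$group == "B"], c(2, 2))
  expect_equal(ncol(co$subjects[["A01"]]$series), 150)
  expect_equal(ncol(co$subjects[["B01"]]$series), 215)
  expect_equal(unname(rowSums(co$truth)), rep(1, 4), tolerance = 1e-12)
  # identical config + seed => bit-identical cohort
  co2 <- quick_cohort(n_per_group = 2, n_roi = 10, seed = 4)
  expect_identical(co$subjects[["B02"]]$series, co2$subjects[["B02"]]$series)
  dir <- tempfile(); man <- write_cohort(co, dir)
  back <- read_cohort(man)
  expect_equal(back$manifest$group, co$manifest$group)
  expect_equal(back$subjects[["A02"]]$series, co$subjects[["A02"]]$series,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("planted occupancy difference separates the groups' truth", {
  co <- simulate_cohort(cohort_config(n_subjects_per_group = 34, n_roi = 10,
                                      seed = 21))
  tt <- t.test(co$truth[co$manifest$group == "A", 1],
               co$truth[co$manifest$group == "B", 1], var.equal = TRUE)
  expect_lt(tt$p.value, 1e-4)
})
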