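# Specific/general classification, edgewise group tests, intersection,
# cluster matching, and resampling bookkeeping.

make_ratios <- function(a_mat, b_mat) {
  structure(list(ratios = rbind(a_mat, b_mat),
                 group = rep(c("A", "B"), c(nrow(a_mat), nrow(b_mat))),
                 group_means = rbind(colMeans(a_mat), colMeans(b_mat))),
            class = "ratio_distribution")
}

test_that("identical group ratios are all classified general", {
  set.seed(1)
  x <- matrix(runif(10 * 3), 10, 3)
  x <- x / rowSums(x)
  cls <- classify_dfcps(make_ratios(x, x))
  expect_false(any(cls$specific))
  expect_equal(attr(cls, "alpha"), 1e-4 / 3)
  # constant equal ratios must give p = 1, not NaN
  c1 <- matrix(rep(c(0.5, 0.5), each = 5), 5, 2)
  cls2 <- classify_dfcps(make_ratios(c1, c1))
  expect_equal(cls2$p, c(1, 1))
})

test_that("a strong occupancy shift is flagged specific and matches t.test", {
  set.seed(2)
  a <- cbind(0.9 + rnorm(34, sd = 0.02), 0.1 - rnorm(34, sd = 0.02))
  b <- cbind(0.1 + rnorm(34, sd = 0.02), 0.9 - rnorm(34, sd = 0.02))
  cls <- classify_dfcps(make_ratios(a, b))
  expect_true(all(cls$specific))
  ref <- t.test(a[, 1], b[, 1], var.equal = TRUE)
  expect_equal(cls$t[1], unname(ref$statistic), tolerance = 1e-10)
  expect_equal(cls$p[1], ref$p.value, tolerance = 1e-10)
})

sym_noise <- function(n, sd = 0.05) {
  m <- matrix(rnorm(n * n, sd = sd), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

test_that("edgewise test recovers a planted edge with no false positives", {
  n <- 12
  hits <- 0; fps <- 0
  for (seed in 1:3) {
    set.seed(seed)
    mats_a <- lapply(1:20, function(i) {
      m <- sym_noise(n); m[2, 5] <- m[5, 2] <- m[2, 5] + 0.6; m })
    mats_b <- lapply(1:20, function(i) sym_noise(n))
    res <- edgewise_test(c(mats_a, mats_b), rep(c("A", "B"), each = 20))
    if (res$mask[2, 5]) hits <- hits + 1
    fps <- fps + (sum(res$mask) - 2 * res$mask[2, 5]) / 2
  }
  expect_equal(hits, 3)
  expect_equal(fps, 0)
  # identical groups: empty mask
  set.seed(9)
  mats <- lapply(1:10, function(i) sym_noise(8))
  res0 <- edgewise_test(c(mats, mats), rep(c("A", "B"), each = 10))
  expect_false(any(res0$mask))
})

test_that("edge bookkeeping matches the 246-region atlas scale", {
  set.seed(4)
  mats <- lapply(1:4, function(i) sym_noise(246, sd = 0.01))
  res <- edgewise_test(mats, c("A", "A", "B", "B"))
  expect_equal(res$n_edges, 30135)
  expect_equal(res$alpha, 1e-4 / 30135)
  expect_equal(nrow(res$table), 30135)
})

mask_from_edges <- function(n, edges) {
  m <- matrix(FALSE, n, n)
  for (e in edges) m[e[1], e[2]] <- m[e[2], e[1]] <- TRUE
  m
}

test_that("edge-mask intersection is the logical AND", {
  m1 <- mask_from_edges(5, list(c(1, 2), c(3, 4)))
  m2 <- mask_from_edges(5, list(c(1, 2)))
  res <- intersect_significant_edges(list(m1, m2))
  expect_equal(res$edges$roi_i, 1)
  expect_equal(res$edges$roi_j, 2)
  empty <- matrix(FALSE, 5, 5)
  expect_equal(nrow(intersect_significant_edges(list(m1, empty))$edges), 0)
  # monotone: adding masks never grows the intersection
  set.seed(8)
  masks <- lapply(1:4, function(i) {
    m <- matrix(sample(c(TRUE, FALSE), 25, replace = TRUE), 5, 5)
    m <- m | t(m); diag(m) <- FALSE; m })
  prev <- sum(intersect_significant_edges(masks[1])$mask)
  for (j in 2:4) {
    cur <- sum(intersect_significant_edges(masks[1:j])$mask)
    expect_lte(cur, prev)
    prev <- cur
  }
  at <- toy_atlas()
  lab <- intersect_significant_edges(list(mask_from_edges(3, list(c(1, 3)))),
                                     atlas = at)
  expect_equal(lab$edges$label_i, "R1")
  expect_equal(lab$edges$label_j, "R3")
})

test_that("greedy correlation matching recovers permutations and noise", {
  set.seed(5)
  a <- matrix(rnorm(4 * 20), 4, 20)
  self <- match_clusters_by_correlation(a, a)
  expect_equal(self$matching$b, self$matching$a)
  expect_equal(self$matching$correlation, rep(1, 4), tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  mp <- match_clusters_by_correlation(a, a[perm, ])
  expect_equal(mp$matching$b[order(mp$matching$a)], order(perm))
  noisy <- a + matrix(rnorm(80, sd = 0.1 * sd(a)), 4, 20)
  mn <- match_clusters_by_correlation(a, noisy)
  expect_true(all(mn$matching$correlation > 0.9))
  withconst <- rbind(a[1:2, ], rep(1, 20))
  mc <- match_clusters_by_correlation(withconst, a)
  expect_equal(mc$excluded$a, 3L)
  expect_false(3 %in% mc$matching$a)
})

test_that("type-I error of classification is controlled on null cohorts", {
  # equal occupancies in both groups: no cluster should ever be specific
  flags <- 0
  for (seed in 1:5) {
    co <- simulate_cohort(cohort_config(
      n_subjects_per_group = 8, n_roi = 24, seed = 300 + seed,
      specific_occupancy = c(1 / 3, 1 / 3)))
    m <- fit_dfcp(co, k = 3)
    cls <- classify_dfcps(m)
    flags <- flags + sum(cls$specific)
  }
  expect_equal(flags, 0)
})

test_that("resampling reports the requested runs with seeds and correlations", {
  co <- quick_cohort(n_per_group = 6, n_roi = 24, seed = 7)
  ref <- fit_dfcp(co, k = 3)
  rep_df <- resample_reproducibility(co, ref, reference_specific = 1,
                                     rates = 1.0, n_runs = 2, seed = 5)
  expect_equal(nrow(rep_df), 2)
  # rate 1 resamples the full cohort: identical model, correlation 1
  expect_equal(rep_df$matched_correlation, c(1, 1), tolerance = 1e-8)
  expect_equal(rep_df$n_subjects, c(12, 12))
  half <- resample_reproducibility(co, ref, 1, rates = 0.5, n_runs = 4,
                                   seed = 6)
  expect_equal(nrow(half), 4)
  expect_equal(half$rate, rep(0.5, 4))
  expect_true(all(!is.na(half$seed)))
  expect_true(all(half$matched_correlation >= -1 & half$matched_correlation <= 1))
})
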