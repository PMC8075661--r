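# Twice-clustering: hierarchical initialization, Lloyd refinement,
# Davies-Bouldin selection, centroids, occupancy ratios.

planted_clouds <- function(k, n_per = 100, sigma = 0.1, sep = 10, dim = 5,
                           seed = 1) {
  set.seed(seed)
  centers <- matrix(0, k, dim)
  for (c in seq_len(k)) centers[c, c %% dim + 1] <- sep * c
  x <- do.call(rbind, lapply(seq_len(k), function(c)
    matrix(rnorm(n_per * dim, sd = sigma), n_per, dim) +
      matrix(centers[c, ], n_per, dim, byrow = TRUE)))
  list(x = x, truth = rep(seq_len(k), each = n_per), centers = centers)
}

sorted_rows <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]

test_that("hierarchical initialization respects degenerate and separated cases", {
  set.seed(4)
  x <- matrix(rnorm(12), 4, 3)
  init <- hierarchical_init(x, 4)
  expect_equal(sorted_rows(init), sorted_rows(x), ignore_attr = TRUE)
  expect_error(hierarchical_init(x, 5), "exceeds")
  pc <- planted_clouds(2, n_per = 50, sigma = 0.2, sep = 20)
  init2 <- hierarchical_init(pc$x, 2)
  for (c in 1:2) {
    d <- sqrt(rowSums((pc$centers - matrix(init2[c, ], 2, 5, byrow = TRUE))^2))
    expect_lt(min(d), 0.5)   # each center inside one cloud
  }
  # duplicating every point leaves the centers unchanged
  dup <- rbind(pc$x, pc$x)
  expect_equal(sorted_rows(hierarchical_init(dup, 2)), sorted_rows(init2),
               tolerance = 1e-8)
})

test_that("Lloyd refinement converges from exact centers and recovers planted clusters", {
  pc <- planted_clouds(3, n_per = 100, sigma = 0.1, sep = 10, seed = 1)
  exact <- do.call(rbind, lapply(1:3, function(c)
    colMeans(pc$x[pc$truth == c, ])))
  fit <- kmeans_refine(pc$x, exact)
  expect_lte(fit$iterations, 2)
  expect_equal(length(unique(paste(fit$labels, pc$truth))), 3)  # bijection
  # single cluster: center is the grand mean
  one <- kmeans_refine(pc$x, matrix(colMeans(pc$x), 1))
  expect_equal(one$centers[1, ], colMeans(pc$x))
  # full twice-clustering agrees perfectly with the planted partition
  fit2 <- twice_cluster(pc$x, 3)
  expect_equal(length(unique(paste(fit2$labels, pc$truth))), 3)
  expect_true(all(diff(fit2$inertia_path) <= 1e-8))
})

test_that("Lloyd refinement matches stats::kmeans run from the same centers", {
  set.seed(10)
  x <- matrix(rnorm(200 * 4), 200, 4)
  init <- hierarchical_init(x, 5)
  ours <- kmeans_refine(x, init)
  ref <- suppressWarnings(stats::kmeans(x, centers = init,
                                        algorithm = "Lloyd", iter.max = 300))
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-8)
  expect_equal(sorted_rows(ours$centers), sorted_rows(ref$centers),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("empty clusters are reseeded with the farthest sample", {
  x <- rbind(matrix(rnorm(40, sd = 0.1), 20, 2),
             matrix(rnorm(40, sd = 0.1) + 10, 20, 2))
  init <- rbind(c(0, 0), c(10, 10), c(100, 100))  # third center sees nothing
  expect_message(fit <- kmeans_refine(x, init), "reseeding")
  expect_equal(sort(unique(fit$labels)), 1:3)
})

test_that("Davies-Bouldin index is 0 for perfectly compact clusters and ranks K correctly", {
  x <- rbind(matrix(1, 5, 3), matrix(9, 5, 3))
  labels <- rep(1:2, each = 5)
  expect_equal(davies_bouldin(x, labels), 0)
  pc <- planted_clouds(2, n_per = 80, sigma = 0.3, sep = 20, seed = 3)
  db <- vapply(2:4, function(k) twice_cluster(pc$x, k)$db, 0)
  expect_lt(db[1], db[2])
  expect_lt(db[1], db[3])
})

test_that("Davies-Bouldin selection finds planted cluster counts", {
  hits <- 0
  for (seed in 1:10) {
    pc <- planted_clouds(3, n_per = 60, sigma = 0.3, sep = 15, seed = seed)
    sel <- select_k_davies_bouldin(pc$x, 2:6)
    if (sel$k == 3) hits <- hits + 1
  }
  expect_gte(hits, 9)
  expect_error(select_k_davies_bouldin(matrix(1, 10, 3)), "identical")
})

fake_model <- function(labels, subject_id, group, weights = NULL,
                       segment_means = NULL, n_roi = 3) {
  k <- max(labels)
  if (is.null(weights)) weights <- rep(1L, length(labels))
  structure(list(k = k, labels = labels,
                 samples = data.frame(subject_id = subject_id, group = group,
                                      start = 1L, end = weights,
                                      weight = weights,
                                      stringsAsFactors = FALSE),
                 segment_means = segment_means, n_roi = n_roi,
                 wqcp = matrix(0, length(labels), n_roi)),
            class = "dfcp_model")
}

test_that("occupancy ratios count samples per subject and sum to one", {
  m <- fake_model(labels = c(1L, 1L, 2L, 3L),
                  subject_id = rep("s1", 4), group = rep("A", 4))
  r <- occupancy_ratios(m)
  expect_equal(as.numeric(r$ratios["s1", ]), c(0.5, 0.25, 0.25))
  m2 <- fake_model(labels = c(2L, 1L, 2L),
                   subject_id = c("a", "a", "b"), group = c("A", "A", "B"))
  r2 <- occupancy_ratios(m2)
  expect_equal(as.numeric(r2$ratios["b", ]), c(0, 1))  # one-hot row
  expect_equal(rowSums(r2$ratios), c(a = 1, b = 1))
  set.seed(1)
  m3 <- fake_model(labels = sample(1:4, 40, replace = TRUE),
                   subject_id = rep(c("a", "b", "c", "d"), each = 10),
                   group = rep(c("A", "B"), each = 20))
  expect_equal(unname(rowSums(occupancy_ratios(m3)$ratios)), rep(1, 4))
})

test_that("pattern centroids average window matrices with segment weights", {
  a <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  b <- matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3, 3)
  m <- fake_model(labels = c(1L, 1L, 2L),
                  subject_id = c("s1", "s2", "s1"),
                  group = c("A", "B", "A"),
                  weights = c(1L, 3L, 2L),
                  segment_means = list(a, b, a))
  cen <- dfcp_centroids(m, scope = "pooled")
  expect_equal(cen[[1]]$matrix, (1 * a + 3 * b) / 4)
  expect_equal(cen[[1]]$n_windows, 4L)
  byg <- dfcp_centroids(m, scope = "by_group")
  expect_equal(byg[[1]]$A$matrix, a)
  expect_equal(byg[[1]]$B$matrix, b)
  expect_true(byg[[2]]$B$absent)     # cluster 2 has no group-B windows
  expect_false(byg[[2]]$A$absent)
  # single cluster of identical matrices reproduces the matrix
  m2 <- fake_model(labels = c(1L, 1L), subject_id = c("x", "y"),
                   group = c("A", "A"), segment_means = list(a, a))
  expect_equal(dfcp_centroids(m2)[[1]]$matrix, a)
})

test_that("subject-level pattern means weight by windows and drop absentees", {
  a <- diag(3) * 0; a[1, 2] <- a[2, 1] <- 1
  b <- a * 0.5
  m <- fake_model(labels = c(1L, 1L, 2L),
                  subject_id = c("s1", "s1", "s2"),
                  group = c("A", "A", "B"),
                  weights = c(1L, 3L, 2L),
                  segment_means = list(a, b, a))
  spm <- subject_pattern_means(m, 1)
  expect_equal(spm$subject_id, "s1")
  expect_equal(spm$matrices[[1]], (1 * a + 3 * b) / 4)
  spm2 <- subject_pattern_means(m, 2)
  expect_equal(spm2$subject_id, "s2")
})
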