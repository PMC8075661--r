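## Twice-clustering: agglomerative hierarchical clustering fixes the initial
## centers, then deterministic Lloyd iterations refine them. Removing the
## random initialization of plain K-means makes the whole stage a pure
## function of its input. Model selection over K uses the Davies-Bouldin
## index (lower is better; ties go to the smallest K).

#' Hierarchical initialization of cluster centers
#'
#' Ward-linkage agglomerative clustering (Euclidean distance, `"ward.D2"`)
#' cut at `k` clusters; the initial centers are the per-cluster means. Ward
#' linkage minimizes within-cluster variance, matching the K-means
#' objective the centers will seed.
#'
#' @param x samples x features matrix.
#' @param k number of clusters (`<= nrow(x)`).
#' @return `k x ncol(x)` matrix of initial centers.
#' @export
hierarchical_init <- function(x, k) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k = ", k, " exceeds number of samples ", nrow(x))
  hc <- hclust(dist(x), method = "ward.D2")
  lab <- cutree(hc, k = k)
  centers <- matrix(0, k, ncol(x))
  for (c in seq_len(k)) {
    centers[c, ] <- colMeans(x[lab == c, , drop = FALSE])
  }
  centers
}

# Squared Euclidean distances from each row of x to each row of centers.
dist_to_centers <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * tcrossprod(x, centers)
}

#' Deterministic Lloyd refinement from given centers
#'
#' Runs Lloyd's algorithm from `init_centers` with no random restarts until
#' the assignment reaches a fixpoint or `max_iter` iterations. Ties in the
#' nearest-center assignment go to the lowest cluster index. An emptied
#' cluster is reseeded with the sample farthest from its own center
#' (logged via `message`). Total within-cluster sum of squares (inertia) is
#' asserted non-increasing across iterations.
#'
#' @param x samples x features matrix.
#' @param init_centers `k x ncol(x)` matrix of starting centers.
#' @param max_iter iteration cap (default 300).
#' @return list with `labels`, `centers`, `inertia`, `iterations`,
#'   `inertia_path`.
#' @export
kmeans_refine <- function(x, init_centers, max_iter = 300) {
  x <- as.matrix(x)
  centers <- as.matrix(init_centers)
  stopifnot(all(is.finite(centers)), ncol(centers) == ncol(x))
  k <- nrow(centers)
  labels <- integer(nrow(x))
  inertia_path <- numeric(0)
  prev_inertia <- Inf
  for (it in seq_len(max_iter)) {
    d2 <- dist_to_centers(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    for (c in seq_len(k)) {
      if (!any(new_labels == c)) {
        donor <- which.max(d2[cbind(seq_len(nrow(x)), new_labels)])
        message("kmeans_refine: reseeding empty cluster ", c,
                " with sample ", donor)
        new_labels[donor] <- c
      }
    }
    inertia <- sum(d2[cbind(seq_len(nrow(x)), new_labels)])
    converged <- identical(new_labels, labels)
    labels <- new_labels
    for (c in seq_len(k))
      centers[c, ] <- colMeans(x[labels == c, , drop = FALSE])
    inertia <- sum(dist_to_centers(x, centers)[cbind(seq_len(nrow(x)), labels)])
    if (inertia > prev_inertia + 1e-8 * max(1, prev_inertia))
      stop("K-means inertia increased: ", prev_inertia, " -> ", inertia)
    inertia_path <- c(inertia_path, inertia)
    prev_inertia <- inertia
    if (converged) break
  }
  list(labels = labels, centers = centers, inertia = prev_inertia,
       iterations = length(inertia_path), inertia_path = inertia_path)
}

#' Davies-Bouldin index of a clustering
#'
#' `DB = mean_i max_{j != i} (s_i + s_j) / d_ij`, with `s_i` the mean
#' Euclidean distance of cluster i's samples to its centroid and `d_ij` the
#' centroid-centroid distance. Lower is better; perfectly compact,
#' separated clusters score 0.
#'
#' @param x samples x features matrix.
#' @param labels cluster assignment in `1..k`.
#' @param centers optional `k x ncol(x)` centroid matrix (recomputed from
#'   labels when `NULL`).
#' @return the index (scalar).
#' @export
davies_bouldin <- function(x, labels, centers = NULL) {
  x <- as.matrix(x)
  k <- max(labels)
  if (is.null(centers)) {
    centers <- matrix(0, k, ncol(x))
    for (c in seq_len(k))
      centers[c, ] <- colMeans(x[labels == c, , drop = FALSE])
  }
  d_own <- sqrt(pmax(dist_to_centers(x, centers), 0))
  s <- vapply(seq_len(k), function(c)
    mean(d_own[labels == c, c]), 0)
  dmat <- as.matrix(dist(centers))
  if (any(dmat[upper.tri(dmat)] == 0))
    stop("coincident cluster centers; Davies-Bouldin index undefined")
  r <- outer(s, s, "+") / dmat
  diag(r) <- -Inf
  mean(apply(r, 1, max))
}

#' Twice-clustering at fixed K
#'
#' @param x samples x features matrix.
#' @param k number of clusters.
#' @return [kmeans_refine()] result plus `init_centers` and `db`.
#' @export
twice_cluster <- function(x, k) {
  init <- hierarchical_init(x, k)
  fit <- kmeans_refine(x, init)
  fit$init_centers <- init
  fit$db <- davies_bouldin(x, fit$labels, fit$centers)
  fit
}

#' Select the number of patterns by the Davies-Bouldin index
#'
#' Runs the full twice-clustering at every K in `k_range` and returns the K
#' minimizing the Davies-Bouldin index (ties broken toward the smallest K).
#'
#' @param x samples x features matrix.
#' @param k_range candidate cluster counts (default `2:30`), clipped to
#'   `nrow(x) - 1`.
#' @return list with `k` (selected), `db_curve` (named numeric), `fits`
#'   (list of [twice_cluster()] results indexed by K).
#' @export
select_k_davies_bouldin <- function(x, k_range = 2:30) {
  x <- as.matrix(x)
  if (nrow(unique(x)) < 2) stop("all samples identical; clustering degenerate")
  k_range <- k_range[k_range >= 2 & k_range <= nrow(x) - 1]
  if (!length(k_range)) stop("empty k_range after clipping to n - 1")
  fits <- list()
  db <- setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    fits[[as.character(k_range[i])]] <- twice_cluster(x, k_range[i])
    db[i] <- fits[[as.character(k_range[i])]]$db
  }
  k_best <- k_range[which.min(db)]   # which.min takes the first (smallest K)
  list(k = k_best, db_curve = db, fits = fits)
}
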