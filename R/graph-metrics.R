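## Graph-theoretic hub detection on pattern centroids: binarize at a grid
## of proportional densities, compute degree and participation coefficient
## per node at each density, integrate each metric over the grid (AUC), and
## select critical regions whose AUC exceeds the network mean by more than
## one standard deviation on BOTH metrics.

#' Binarize a weighted matrix at a proportional density
#'
#' Keeps the `round(density * n_edges)` edges with the largest absolute
#' weight (anticorrelations count as connections); ties at the cutoff are
#' broken by ascending (i, j) lexicographic edge order so the result is
#' deterministic.
#'
#' @param m symmetric weighted matrix with zero diagonal.
#' @param density fraction of the `n (n - 1) / 2` possible edges to retain,
#'   in `(0, 1]`; a density that rounds to zero edges is an error.
#' @return list of class `thresholded_graph`: `adjacency` (binary symmetric
#'   matrix), `density`, `n_edges_kept`.
#' @export
proportional_threshold <- function(m, density) {
  m <- as.matrix(m)
  n <- nrow(m)
  stopifnot(n == ncol(m), density > 0, density <= 1)
  if (max(abs(diag(m))) > 0) stop("matrix must have zero diagonal")
  ut <- upper_tri_index(n)
  n_edges <- length(ut)
  keep <- round(density * n_edges)
  if (keep < 1) stop("density ", density, " retains zero edges")
  ord <- order(-abs(m[ut]), seq_along(ut))   # |w| desc, ties by edge index asc
  sel <- ut[ord[seq_len(keep)]]
  adj <- matrix(0L, n, n)
  adj[sel] <- 1L
  adj <- adj + t(adj)
  structure(list(adjacency = adj, density = density,
                 n_edges_kept = as.integer(keep)),
            class = "thresholded_graph")
}

#' Node degree
#'
#' @param graph a [proportional_threshold()] result or a binary symmetric
#'   adjacency matrix.
#' @return integer vector of row sums.
#' @export
node_degree <- function(graph) {
  adj <- if (inherits(graph, "thresholded_graph")) graph$adjacency else
    as.matrix(graph)
  as.integer(rowSums(adj))
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_s (k_is / k_i)^2`, where `k_is` counts node i's edges into
#' module s. Isolated nodes (`k_i = 0`) get `P_i = 0`. When `modules` is
#' omitted, the partition is obtained by greedy modularity maximization
#' (fast-greedy community detection) on the same graph, which is
#' deterministic.
#'
#' @param graph a [proportional_threshold()] result or binary adjacency.
#' @param modules optional integer partition vector covering every node.
#' @return numeric vector in `[0, 1]`.
#' @export
participation_coefficient <- function(graph, modules = NULL) {
  adj <- if (inherits(graph, "thresholded_graph")) graph$adjacency else
    as.matrix(graph)
  n <- nrow(adj)
  if (is.null(modules)) modules <- modularity_partition(adj)
  if (length(modules) != n || any(is.na(modules)))
    stop("module partition must cover all ", n, " nodes")
  modules <- as.integer(factor(modules))
  deg <- rowSums(adj)
  p <- numeric(n)
  for (s in seq_len(max(modules))) {
    kis <- rowSums(adj[, modules == s, drop = FALSE])
    nz <- deg > 0
    p[nz] <- p[nz] + (kis[nz] / deg[nz])^2
  }
  ifelse(deg > 0, 1 - p, 0)
}

# Deterministic modularity partition of a binary graph (greedy
# agglomerative modularity maximization).
modularity_partition <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::membership(igraph::cluster_fast_greedy(g)))
}

#' Trapezoidal AUC of a metric over the density grid
#'
#' @param values numeric vector, one metric value per density.
#' @param densities strictly increasing grid (>= 2 points).
#' @return scalar integral.
#' @export
metric_auc <- function(values, densities) {
  if (any(!is.finite(values)))
    stop("non-finite metric value at density ",
         densities[which(!is.finite(values))[1]])
  trapezoid(densities, values)
}

#' Degree and participation coefficient across a density grid
#'
#' Thresholds `m` at every density in the grid, computes both local metrics
#' per node, and integrates each metric over the grid. Non-finite metric
#' values abort with the offending node and density.
#'
#' @param m symmetric weighted matrix with zero diagonal (e.g. a pattern
#'   centroid).
#' @param densities grid of proportional densities (default 0.10 to 0.40 in
#'   steps of 0.01).
#' @param modules optional fixed partition forwarded to
#'   [participation_coefficient()]; by default each thresholded graph gets
#'   its own modularity partition.
#' @return object of class `metric_table`: list with `degree` and
#'   `participation` (nodes x densities matrices), `auc_degree`,
#'   `auc_participation` (vectors), `densities`.
#' @export
graph_metric_table <- function(m, densities = seq(0.10, 0.40, by = 0.01),
                               modules = NULL) {
  stopifnot(length(densities) >= 2, all(diff(densities) > 0))
  n <- nrow(m)
  deg <- matrix(NA_real_, n, length(densities))
  part <- matrix(NA_real_, n, length(densities))
  for (i in seq_along(densities)) {
    g <- proportional_threshold(m, densities[i])
    deg[, i] <- node_degree(g)
    part[, i] <- participation_coefficient(g, modules)
  }
  for (mt in list(deg, part)) {
    bad <- which(!is.finite(mt), arr.ind = TRUE)
    if (nrow(bad))
      stop("non-finite metric for node ", bad[1, 1], " at density ",
           densities[bad[1, 2]])
  }
  structure(list(degree = deg, participation = part,
                 auc_degree = apply(deg, 1, metric_auc, densities = densities),
                 auc_participation = apply(part, 1, metric_auc,
                                           densities = densities),
                 densities = densities),
            class = "metric_table")
}

#' Select critical regions from metric AUCs
#'
#' Per metric, selects nodes whose AUC strictly exceeds
#' `mean + 1 * sd` over all nodes (sample standard deviation, n - 1
#' denominator). Critical regions are the intersection of the two
#' selections. A metric with zero spread selects nothing.
#'
#' @param metrics a [graph_metric_table()] result.
#' @return object of class `critical_roi_set`: list with `by_degree`,
#'   `by_participation`, `intersection` (integer node indices) and `stats`
#'   (mean/sd/cutoff per metric).
#' @export
select_critical_rois <- function(metrics) {
  stopifnot(inherits(metrics, "metric_table"))
  pick <- function(auc) {
    s <- sd(auc)
    cutoff <- mean(auc) + s
    list(sel = if (s == 0) integer(0) else which(auc > cutoff),
         mean = mean(auc), sd = s, cutoff = cutoff)
  }
  dsel <- pick(metrics$auc_degree)
  psel <- pick(metrics$auc_participation)
  structure(list(by_degree = dsel$sel, by_participation = psel$sel,
                 intersection = intersect(dsel$sel, psel$sel),
                 stats = data.frame(
                   metric = c("degree", "participation"),
                   mean = c(dsel$mean, psel$mean),
                   sd = c(dsel$sd, psel$sd),
                   cutoff = c(dsel$cutoff, psel$cutoff))),
            class = "critical_roi_set")
}

#' @export
print.critical_roi_set <- function(x, ...) {
  cat("Critical regions (AUC > mean + 1 sd on both metrics):\n")
  cat("  by degree:       ", paste(x$by_degree, collapse = " "), "\n")
  cat("  by participation:", paste(x$by_participation, collapse = " "), "\n")
  cat("  intersection:    ", paste(x$intersection, collapse = " "), "\n")
  invisible(x)
}
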