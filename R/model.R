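## The fitted dynamic-functional-connectome-pattern model: pooled WQCP
## samples from every subject, twice-clustered into K patterns (DFCPs),
## with enough per-segment bookkeeping retained to rebuild pattern
## centroids and subject-level summaries afterwards.

#' Fit a dynamic functional connectome pattern (DFCP) model
#'
#' Runs the full sample-construction and clustering stages over a cohort:
#' per subject, sliding-window dFC, strength matrix, automatic segmentation
#' into quasistable epochs, and WQCP samples; then pools all samples and
#' applies twice-clustering (hierarchical initialization + deterministic
#' K-means). With `k = NULL` the number of patterns is chosen by the
#' Davies-Bouldin index over `k_range`.
#'
#' @param cohort a `dfc_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param duration_s sliding-window duration in seconds (default 36);
#'   converted per subject to a window length in time points via the
#'   subject's TR.
#' @param w optional explicit window length in time points (overrides
#'   `duration_s` for every subject; used for sensitivity runs).
#' @param step window step in time points (default 1).
#' @param k fixed number of patterns, or `NULL` to select by
#'   Davies-Bouldin.
#' @param k_range candidate K values when `k` is `NULL` (default `2:30`).
#' @return object of class `dfcp_model` with components
#'   \describe{
#'     \item{k}{number of patterns}
#'     \item{labels}{cluster id per WQCP sample}
#'     \item{centers, init_centers}{final and initial `k x n_roi` centers in
#'       WQCP space}
#'     \item{db_curve}{Davies-Bouldin index per candidate K (`NULL` when
#'       `k` was fixed)}
#'     \item{samples}{data.frame of sample metadata (subject_id, group,
#'       start, end, weight)}
#'     \item{wqcp}{samples x regions matrix of WQCP vectors}
#'     \item{segment_means}{per-sample mean dFC matrix (list)}
#'     \item{inertia, iterations}{K-means diagnostics}
#'   }
#' @export
fit_dfcp <- function(cohort, duration_s = 36, w = NULL, step = 1,
                     k = NULL, k_range = 2:30) {
  stopifnot(inherits(cohort, "dfc_cohort"))
  per <- lapply(cohort$subjects, segment_subject, w = w,
                duration_s = duration_s, step = step)
  wqcp <- do.call(rbind, lapply(per, function(p) p$wqcp$vectors))
  samples <- do.call(rbind, lapply(per, function(p) p$wqcp$meta))
  rownames(samples) <- NULL
  segment_means <- do.call(c, unname(lapply(per, function(p) p$segment_means)))
  db_curve <- NULL
  if (is.null(k)) {
    sel <- select_k_davies_bouldin(wqcp, k_range)
    k <- sel$k
    db_curve <- sel$db_curve
    fit <- sel$fits[[as.character(k)]]
  } else {
    fit <- twice_cluster(wqcp, k)
  }
  structure(list(k = k, labels = fit$labels, centers = fit$centers,
                 init_centers = fit$init_centers, db_curve = db_curve,
                 samples = samples, wqcp = wqcp,
                 segment_means = segment_means,
                 inertia = fit$inertia, iterations = fit$iterations,
                 n_roi = ncol(wqcp), duration_s = duration_s,
                 w = w, step = step,
                 manifest = cohort$manifest),
            class = "dfcp_model")
}

#' @export
print.dfcp_model <- function(x, ...) {
  cat(sprintf("<dfcp_model: %d patterns over %d WQCP samples (%d subjects, %d regions)>\n",
              x$k, nrow(x$wqcp), length(unique(x$samples$subject_id)), x$n_roi))
  if (!is.null(x$db_curve))
    cat(sprintf("  K selected by Davies-Bouldin over K = %s..%s\n",
                names(x$db_curve)[1], names(x$db_curve)[length(x$db_curve)]))
  cat(sprintf("  K-means: inertia %.4g after %d iteration(s)\n",
              x$inertia, x$iterations))
  invisible(x)
}

#' @export
summary.dfcp_model <- function(object, ...) {
  tab <- table(factor(object$labels, levels = seq_len(object$k)))
  ratios <- occupancy_ratios(object)
  out <- list(k = object$k, cluster_sizes = as.integer(tab),
              mean_ratio_by_group = ratios$group_means,
              n_samples = nrow(object$wqcp),
              n_subjects = length(unique(object$samples$subject_id)))
  class(out) <- "summary.dfcp_model"
  out
}

#' @export
print.summary.dfcp_model <- function(x, ...) {
  cat(sprintf("DFCP model: K = %d, %d samples from %d subjects\n",
              x$k, x$n_samples, x$n_subjects))
  cat("Cluster sizes:", paste(x$cluster_sizes, collapse = " "), "\n")
  cat("Mean occupancy ratio by group:\n")
  print(round(x$mean_ratio_by_group, 3))
  invisible(x)
}

#' Plot a DFCP model
#'
#' With `which = "db"` (default, available when K was selected
#' automatically) plots the Davies-Bouldin curve with the chosen K marked;
#' with `which = "centers"` shows the K cluster centers in WQCP space as an
#' image.
#'
#' @param x a `dfcp_model`.
#' @param which `"db"` or `"centers"`.
#' @param ... passed to the underlying plotting function.
#' @return the model, invisibly.
#' @export
plot.dfcp_model <- function(x, which = c("db", "centers"), ...) {
  which <- match.arg(which)
  if (which == "db") {
    if (is.null(x$db_curve)) stop("model was fitted at fixed K; no DB curve")
    ks <- as.integer(names(x$db_curve))
    graphics::plot(ks, x$db_curve, type = "b", xlab = "K",
                   ylab = "Davies-Bouldin index", ...)
    graphics::abline(v = x$k, lty = 2)
  } else {
    graphics::image(t(x$centers), xlab = "region", ylab = "pattern",
                    axes = FALSE, ...)
    graphics::axis(2, at = seq(0, 1, length.out = x$k),
                   labels = seq_len(x$k))
  }
  invisible(x)
}

#' Per-subject occupancy ratios over patterns
#'
#' `ratio[subject, k]` is the fraction of the subject's WQCP samples
#' assigned to pattern k (sample counts, not window-weighted). Every row
#' sums to 1.
#'
#' @param model a `dfcp_model`.
#' @return object of class `ratio_distribution`: list with `ratios`
#'   (subjects x K matrix), `group` (label per row), `group_means`
#'   (groups x K matrix).
#' @export
occupancy_ratios <- function(model) {
  stopifnot(inherits(model, "dfcp_model"))
  subs <- unique(model$samples$subject_id)
  ratios <- matrix(0, length(subs), model$k,
                   dimnames = list(subs, paste0("dfcp", seq_len(model$k))))
  grp <- character(length(subs))
  for (i in seq_along(subs)) {
    sel <- model$samples$subject_id == subs[i]
    if (!any(sel)) stop("subject ", subs[i], " has no WQCP samples")
    ratios[i, ] <- tabulate(model$labels[sel], model$k) / sum(sel)
    grp[i] <- model$samples$group[sel][1]
  }
  gm <- do.call(rbind, lapply(split(seq_along(subs), grp), function(idx)
    colMeans(ratios[idx, , drop = FALSE])))
  structure(list(ratios = ratios, group = grp, group_means = gm),
            class = "ratio_distribution")
}

#' Pattern centroids as mean dFC matrices
#'
#' For each pattern, averages all window-level dFC matrices belonging to
#' segments labeled with that pattern (via the stored per-segment means,
#' weighted by segment length in windows). Scope `"pooled"` averages over
#' both groups; `"by_group"` returns one centroid per group, flagged absent
#' when a group contributes no windows.
#'
#' @param model a `dfcp_model`.
#' @param scope `"pooled"` or `"by_group"`.
#' @return list over patterns. Pooled scope: each element has `matrix`,
#'   `n_windows`, `absent`. Group scope: each element is a list over groups
#'   of the same structure.
#' @export
dfcp_centroids <- function(model, scope = c("pooled", "by_group")) {
  scope <- match.arg(scope)
  centroid_of <- function(idx) {
    if (!length(idx))
      return(list(matrix = NULL, n_windows = 0L, absent = TRUE))
    wts <- model$samples$weight[idx]
    acc <- matrix(0, model$n_roi, model$n_roi)
    for (j in seq_along(idx))
      acc <- acc + wts[j] * model$segment_means[[idx[j]]]
    list(matrix = acc / sum(wts), n_windows = as.integer(sum(wts)),
         absent = FALSE)
  }
  lapply(seq_len(model$k), function(c) {
    in_c <- which(model$labels == c)
    if (scope == "pooled") centroid_of(in_c)
    else {
      groups <- sort(unique(model$samples$group))
      setNames(lapply(groups, function(g)
        centroid_of(in_c[model$samples$group[in_c] == g])), groups)
    }
  })
}

#' Per-subject mean dFC matrix within one pattern
#'
#' Each subject contributes the window-weighted mean of its segment-mean
#' dFC matrices whose segments carry pattern label `k`; subjects with no
#' windows in the pattern are omitted. This is the subject-level unit of
#' analysis for edgewise group tests.
#'
#' @param model a `dfcp_model`.
#' @param k pattern id.
#' @return list with `matrices` (list per retained subject), `subject_id`,
#'   `group`.
#' @export
subject_pattern_means <- function(model, k) {
  stopifnot(k >= 1, k <= model$k)
  keep_s <- character(0); keep_g <- character(0); mats <- list()
  for (sid in unique(model$samples$subject_id)) {
    idx <- which(model$samples$subject_id == sid & model$labels == k)
    if (!length(idx)) next
    wts <- model$samples$weight[idx]
    acc <- matrix(0, model$n_roi, model$n_roi)
    for (j in seq_along(idx))
      acc <- acc + wts[j] * model$segment_means[[idx[j]]]
    mats[[length(mats) + 1L]] <- acc / sum(wts)
    keep_s <- c(keep_s, sid)
    keep_g <- c(keep_g, model$samples$group[idx[1]])
  }
  list(matrices = mats, subject_id = keep_s, group = keep_g)
}
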