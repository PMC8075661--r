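## Group inference: which patterns are group-specific, which connectome
## edges differ between groups inside the shared (general) patterns, and
## how reproducible the specific pattern is under subject resampling and
## alternative window lengths. All tests are two-sample Student
## (equal-variance) t-tests with Bonferroni-style fixed thresholds.

#' Classify patterns as specific or general
#'
#' Per pattern, a two-sample equal-variance t-test compares the per-subject
#' occupancy ratios between the two groups; the pattern is specific iff
#' `p < alpha_numerator / K` (default numerator 0.0001). Patterns whose
#' ratios are constant and equal in both groups yield p = 1 (general), never
#' NaN.
#'
#' @param ratios a [occupancy_ratios()] result or a `dfcp_model`.
#' @param alpha_numerator numerator of the Bonferroni-style threshold.
#' @return data.frame with columns `dfcp`, `t`, `p`, `specific`, and
#'   attribute `alpha` (the threshold used).
#' @export
classify_dfcps <- function(ratios, alpha_numerator = 1e-4) {
  if (inherits(ratios, "dfcp_model")) ratios <- occupancy_ratios(ratios)
  stopifnot(inherits(ratios, "ratio_distribution"))
  groups <- sort(unique(ratios$group))
  if (length(groups) != 2) stop("need exactly 2 groups, got ", length(groups))
  a <- ratios$ratios[ratios$group == groups[1], , drop = FALSE]
  b <- ratios$ratios[ratios$group == groups[2], , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) stop("need >= 2 subjects per group")
  k <- ncol(ratios$ratios)
  res <- col_t_test(a, b)
  alpha <- alpha_numerator / k
  out <- data.frame(dfcp = seq_len(k), t = res$t, p = res$p,
                    specific = res$p < alpha)
  attr(out, "alpha") <- alpha
  out
}

#' Edgewise group difference within one pattern
#'
#' Unit of analysis is the subject: each subject contributes its mean dFC
#' matrix over its windows in the pattern ([subject_pattern_means()]).
#' Per upper-triangle edge a two-sample equal-variance t-test compares the
#' groups; the significance mask uses `p < alpha_numerator / n_edges`
#' with `n_edges = n_roi (n_roi - 1) / 2` (30,135 at 246 regions).
#'
#' @param model a `dfcp_model`.
#' @param k pattern id.
#' @param alpha_numerator threshold numerator (default 0.0001).
#' @return `NULL` (with a warning) if either group retains fewer than 2
#'   subjects; otherwise a list with `mask` (symmetric logical matrix),
#'   `table` (data.frame: roi_i, roi_j, t, p for every edge), `alpha`,
#'   `n_edges`, `n_subjects` (per group).
#' @export
edgewise_group_difference <- function(model, k, alpha_numerator = 1e-4) {
  spm <- subject_pattern_means(model, k)
  groups <- sort(unique(spm$group))
  if (length(groups) < 2 ||
      min(table(factor(spm$group, levels = groups))) < 2) {
    warning("pattern ", k, ": fewer than 2 subjects in a group; skipped")
    return(NULL)
  }
  edgewise_test(spm$matrices, spm$group, alpha_numerator)
}

#' Edgewise two-sample test over subject connectivity matrices
#'
#' The matrix-level workhorse behind [edgewise_group_difference()]: given
#' one symmetric connectivity matrix per subject and a two-level group
#' label, tests every upper-triangle edge with a Student equal-variance
#' t-test and thresholds at `alpha_numerator / n_edges`.
#'
#' @param matrices list of symmetric `n x n` matrices, one per subject.
#' @param groups group label per matrix (exactly two levels, >= 2 each).
#' @param alpha_numerator threshold numerator (default 0.0001).
#' @return list with `mask` (symmetric logical matrix), `table`
#'   (data.frame: roi_i, roi_j, t, p), `alpha`, `n_edges`, `n_subjects`.
#' @export
edgewise_test <- function(matrices, groups, alpha_numerator = 1e-4) {
  lev <- sort(unique(groups))
  stopifnot(length(lev) == 2, min(table(groups)) >= 2)
  n <- nrow(matrices[[1]])
  ut <- upper_tri_index(n)
  flat <- t(vapply(matrices, function(m) m[ut], numeric(length(ut))))
  a <- flat[groups == lev[1], , drop = FALSE]
  b <- flat[groups == lev[2], , drop = FALSE]
  res <- col_t_test(a, b)
  n_edges <- n * (n - 1) / 2
  alpha <- alpha_numerator / n_edges
  sig <- res$p < alpha
  mask <- matrix(FALSE, n, n)
  mask[ut] <- sig
  mask <- mask | t(mask)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(mask = mask,
       table = data.frame(roi_i = ij[, 1], roi_j = ij[, 2],
                          t = res$t, p = res$p),
       alpha = alpha, n_edges = n_edges,
       n_subjects = table(factor(groups, levels = lev)))
}

#' Intersect significant-edge masks across patterns
#'
#' Logical AND of the edge masks of all general patterns: the edges that
#' differ between groups in every shared pattern.
#'
#' @param masks list of symmetric logical matrices (as produced by
#'   [edgewise_group_difference()]); `NULL` entries are dropped.
#' @param atlas optional [load_atlas()] table used to label the edges.
#' @return list with `mask` (symmetric logical) and `edges` (data.frame:
#'   roi_i, roi_j and, when an atlas is given, label_i, label_j).
#' @export
intersect_significant_edges <- function(masks, atlas = NULL) {
  masks <- Filter(Negate(is.null), masks)
  if (!length(masks)) stop("need at least one edge mask")
  inter <- Reduce(`&`, masks)
  ij <- which(inter & upper.tri(inter), arr.ind = TRUE)
  edges <- data.frame(roi_i = ij[, 1], roi_j = ij[, 2])
  if (!is.null(atlas) && nrow(edges)) {
    edges$label_i <- atlas$abbreviation[edges$roi_i]
    edges$label_j <- atlas$abbreviation[edges$roi_j]
  }
  list(mask = inter, edges = edges)
}

#' Match two center sets by greedy maximum correlation
#'
#' Computes the Pearson correlation between every pair of centers (rows)
#' and matches greedily: the highest remaining correlation is taken,
#' its row and column removed, until one side is exhausted. Centers with
#' zero variance cannot be correlated and are excluded with a flag.
#'
#' @param centers_a,centers_b matrices of centers (rows) in WQCP space.
#' @return list with `matching` (data.frame: a, b, correlation) and
#'   `excluded` (integer indices of constant centers in either set, coded
#'   by list `a`/`b`).
#' @export
match_clusters_by_correlation <- function(centers_a, centers_b) {
  centers_a <- as.matrix(centers_a); centers_b <- as.matrix(centers_b)
  const_a <- which(apply(centers_a, 1, sd) == 0)
  const_b <- which(apply(centers_b, 1, sd) == 0)
  keep_a <- setdiff(seq_len(nrow(centers_a)), const_a)
  keep_b <- setdiff(seq_len(nrow(centers_b)), const_b)
  cm <- suppressWarnings(
    cor(t(centers_a[keep_a, , drop = FALSE]),
        t(centers_b[keep_b, , drop = FALSE])))
  rows <- list()
  while (length(keep_a) && length(keep_b) && length(cm)) {
    best <- which(cm == max(cm), arr.ind = TRUE)[1, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      a = keep_a[best[1]], b = keep_b[best[2]],
      correlation = cm[best[1], best[2]])
    keep_a <- keep_a[-best[1]]; keep_b <- keep_b[-best[2]]
    cm <- cm[-best[1], -best[2], drop = FALSE]
  }
  matching <- if (length(rows)) do.call(rbind, rows)
    else data.frame(a = integer(0), b = integer(0), correlation = numeric(0))
  list(matching = matching[order(matching$a), , drop = FALSE],
       excluded = list(a = const_a, b = const_b))
}

#' Reproducibility of the specific pattern under subject resampling
#'
#' For each sampling rate and run, draws a subject-level subsample without
#' replacement within each group, refits the model at the reference model's
#' K, classifies patterns, and reports the correlation (in WQCP space)
#' between the rerun's specific-pattern center and the reference
#' specific-pattern center (via greedy matching of the full center sets).
#'
#' @param cohort the full `dfc_cohort`.
#' @param reference_model the `dfcp_model` fitted on the full cohort.
#' @param reference_specific id of the specific pattern in the reference
#'   model (e.g. from [classify_dfcps()]).
#' @param rates sampling rates (default `c(0.5, 0.9)`).
#' @param n_runs runs per rate (default 4).
#' @param seed integer seed for the resampling draws.
#' @param duration_s,w,step forwarded to [fit_dfcp()].
#' @return data.frame with one row per run: `rate`, `run`, `seed`,
#'   `n_subjects`, `specific_dfcp` (rerun's specific pattern id, NA if
#'   none), `matched_correlation`.
#' @export
resample_reproducibility <- function(cohort, reference_model,
                                     reference_specific,
                                     rates = c(0.5, 0.9), n_runs = 4,
                                     seed = 1, duration_s = 36, w = NULL,
                                     step = 1) {
  stopifnot(inherits(cohort, "dfc_cohort"), inherits(reference_model, "dfcp_model"))
  ref_center <- reference_model$centers[reference_specific, , drop = FALSE]
  out <- list(); r <- 0L
  for (rate in rates) {
    for (run in seq_len(n_runs)) {
      r <- r + 1L
      run_seed <- derive_seed(seed, r)
      ids <- with_seed(run_seed, unlist(lapply(
        split(cohort$manifest$subject_id, cohort$manifest$group),
        function(s) sample(s, max(2, round(rate * length(s)))))))
      sub <- cohort
      sub$subjects <- cohort$subjects[ids]
      sub$manifest <- cohort$manifest[cohort$manifest$subject_id %in% ids, ]
      res <- tryCatch({
        m <- fit_dfcp(sub, duration_s = duration_s, w = w, step = step,
                      k = reference_model$k)
        cls <- classify_dfcps(m)
        spec <- cls$dfcp[cls$specific]
        mm <- match_clusters_by_correlation(ref_center, m$centers)
        matched_cor <- if (nrow(mm$matching)) mm$matching$correlation[1] else NA_real_
        data.frame(rate = rate, run = run, seed = run_seed,
                   n_subjects = length(ids),
                   specific_dfcp = if (length(spec)) spec[1] else NA_integer_,
                   matched_correlation = matched_cor)
      }, error = function(e) {
        warning("resampling run skipped (rate ", rate, ", run ", run, "): ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(res)) out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}
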