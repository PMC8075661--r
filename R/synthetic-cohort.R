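## Synthetic two-group cohort with planted latent connectivity states.
##
## Each subject's regional signal switches between a small set of latent
## states; within a state the signal at every time point is a draw from a
## zero-mean multivariate normal with that state's covariance, plus
## independent observation noise. One state's stationary occupancy differs
## between the two groups, giving every downstream stage a known
## group-specific pattern to recover.

#' Build block-structured state covariance matrices
#'
#' Constructs `n_states` distinct correlation-like covariance matrices with
#' unit diagonal and modular block structure: region pairs within a block
#' correlate at `within_r`, pairs across blocks at `between_r`. Block sizes
#' are deliberately unequal (proportional to `2, 3, ..., n_blocks + 1`) and
#' each state uses its own random permutation of regions into blocks, so
#' states differ both in which regions co-fluctuate and in each region's
#' total connectivity strength — the feature the downstream strength-profile
#' clustering sees. Matrices that are not positive definite after
#' construction are repaired by flooring eigenvalues and rescaling to unit
#' diagonal.
#'
#' @param n_roi number of regions.
#' @param n_states number of matrices to generate.
#' @param n_blocks number of modules per state (>= 2).
#' @param within_r within-block correlation, in `[0, 1)`; must exceed
#'   `between_r`.
#' @param between_r between-block correlation, in `[0, within_r)`.
#' @param seed integer seed controlling the block permutations.
#' @return list of `n_states` symmetric positive-definite matrices.
#' @export
make_state_covariances <- function(n_roi, n_states, n_blocks = 4,
                                   within_r = 0.9, between_r = 0,
                                   seed = 1) {
  stopifnot(n_roi >= 3, n_states >= 1, n_blocks >= 2,
            between_r >= 0, between_r <= within_r, within_r < 1)
  w <- (seq_len(n_blocks) + 1)^2
  sizes <- diff(round(cumsum(c(0, w)) / sum(w) * n_roi))
  if (any(sizes < 1)) stop("n_roi too small for ", n_blocks, " blocks")
  block_of <- rep(seq_len(n_blocks), times = sizes)
  with_seed(seed, lapply(seq_len(n_states), function(s) {
    perm <- sample.int(n_roi)
    b <- block_of[order(perm)]   # region i belongs to block b[i]
    m <- matrix(between_r, n_roi, n_roi)
    for (k in seq_len(n_blocks)) {
      idx <- which(b == k)
      m[idx, idx] <- within_r
    }
    diag(m) <- 1
    ensure_positive_definite(m, context = sprintf("state %d", s))
  }))
}

# Eigenvalue-floor repair; hard error if the repaired matrix still fails a
# Cholesky factorization.
ensure_positive_definite <- function(m, floor_frac = 1e-6, context = "matrix") {
  ev <- eigen(m, symmetric = TRUE)
  if (min(ev$values) > floor_frac * max(ev$values)) return(m)
  lam <- pmax(ev$values, floor_frac * max(ev$values))
  r <- ev$vectors %*% (lam * t(ev$vectors))
  d <- sqrt(diag(r))
  r <- r / outer(d, d)          # restore unit diagonal
  r <- (r + t(r)) / 2
  ok <- tryCatch({ chol(r); TRUE }, error = function(e) FALSE)
  if (!ok) stop("positive-definite repair failed for ", context)
  r
}

#' Define a latent connectivity state
#'
#' @param state_id integer identifier.
#' @param covariance symmetric positive-definite matrix (regions x regions).
#' @param occupancy named numeric: stationary occupancy probability of this
#'   state per group label; per group, occupancies across all states of a
#'   cohort must sum to 1.
#' @param mean_dwell expected number of consecutive time points spent in the
#'   state per visit (>= 2), controlling how "quasistable" epochs are.
#' @return an object of class `state_spec`.
#' @export
state_spec <- function(state_id, covariance, occupancy, mean_dwell = 60) {
  stopifnot(is.matrix(covariance), nrow(covariance) == ncol(covariance),
            isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8)),
            mean_dwell >= 2, all(occupancy >= 0), !is.null(names(occupancy)))
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("state covariance is not positive definite")
  structure(list(state_id = as.integer(state_id), covariance = covariance,
                 occupancy = occupancy, mean_dwell = mean_dwell),
            class = "state_spec")
}

#' Cohort simulation configuration
#'
#' Defaults mirror a two-site resting-state design: 34 subjects per group,
#' 246 regions, group A acquired at TR 3.0 s with 150 retained volumes and
#' group B at TR 2.0 s with 215 retained volumes. If `states` is omitted, a
#' four-state system is built in which state 1 occupies 45% of group A's
#' time but only 5% of group B's (the planted group-specific pattern), with
#' the remainder split evenly over the background states so that no
#' background state carries a concentrated group difference of its own.
#'
#' @param n_subjects_per_group subjects per group (default 34).
#' @param n_roi regions (default 246; use smaller values for quick runs).
#' @param tr_by_group named numeric, seconds per volume for groups A and B.
#' @param n_timepoints_by_group named integer, retained volumes per group.
#' @param states list of [state_spec()] objects; `NULL` for the default
#'   planted-difference system.
#' @param n_states number of states for the default system.
#' @param specific_occupancy length-2 numeric: occupancy of state 1 in
#'   groups A and B for the default system (default `c(0.45, 0.05)`).
#' @param mean_dwell expected dwell per state visit, in time points.
#' @param observation_noise_sd standard deviation of i.i.d. Gaussian
#'   observation noise added to the state signal (default 0.5).
#' @param seed master integer seed; all subject seeds derive from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects_per_group = 34, n_roi = 246,
                          tr_by_group = c(A = 3.0, B = 2.0),
                          n_timepoints_by_group = c(A = 150L, B = 215L),
                          states = NULL, n_states = 4,
                          specific_occupancy = c(0.45, 0.05),
                          mean_dwell = 60, observation_noise_sd = 0.1,
                          seed = 1) {
  stopifnot(n_roi >= 3, n_subjects_per_group >= 1,
            all(n_timepoints_by_group >= 2),
            identical(sort(names(tr_by_group)), sort(names(n_timepoints_by_group))))
  if (is.null(states)) {
    stopifnot(n_states >= 2, specific_occupancy >= 0, specific_occupancy <= 1)
    n_blocks <- max(2, min(4, n_roi %/% 6))
    covs <- make_state_covariances(n_roi, n_states, n_blocks = n_blocks,
                                   seed = derive_seed(seed, 0))
    states <- lapply(seq_len(n_states), function(s) {
      occ <- if (s == 1) specific_occupancy else
        (1 - specific_occupancy) / (n_states - 1)
      state_spec(s, covs[[s]],
                 occupancy = c(A = occ[1], B = occ[2]),
                 mean_dwell = mean_dwell)
    })
  }
  for (g in names(tr_by_group)) {
    tot <- sum(vapply(states, function(s) s$occupancy[[g]], 0))
    if (abs(tot - 1) > 1e-8)
      stop("occupancies for group ", g, " sum to ", tot, ", not 1")
  }
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 n_roi = as.integer(n_roi), tr_by_group = tr_by_group,
                 n_timepoints_by_group = n_timepoints_by_group,
                 states = states,
                 observation_noise_sd = observation_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Sample a latent state sequence
#'
#' First-order Markov chain with transition kernel
#' \eqn{P = (1-\lambda) I + \lambda \mathbf{1}\pi^\top} where \eqn{\pi} is
#' the group's occupancy vector and \eqn{\lambda = 1/\code{mean\_dwell}}.
#' The stationary distribution is exactly \eqn{\pi}; state \eqn{i}'s expected
#' dwell per visit is \eqn{\code{mean\_dwell}/(1-\pi_i)}, i.e. at least
#' `mean_dwell`, producing geometric quasistable epochs.
#'
#' @param n_timepoints length of the sequence.
#' @param states list of [state_spec()] objects.
#' @param group group label indexing `occupancy`.
#' @param seed integer seed.
#' @return integer vector of state ids (positions in `states`).
#' @export
sample_state_sequence <- function(n_timepoints, states, group, seed) {
  pi_g <- vapply(states, function(s) {
    if (!group %in% names(s$occupancy))
      stop("no occupancy defined for group ", group)
    s$occupancy[[group]]
  }, 0)
  stopifnot(abs(sum(pi_g) - 1) < 1e-8)
  dwell <- mean(vapply(states, function(s) s$mean_dwell, 0))
  lambda <- 1 / dwell
  with_seed(seed, {
    z <- integer(n_timepoints)
    z[1] <- sample.int(length(states), 1, prob = pi_g)
    if (n_timepoints > 1) {
      resample <- runif(n_timepoints - 1) < lambda
      for (t in 2:n_timepoints) {
        z[t] <- if (resample[t - 1])
          sample.int(length(states), 1, prob = pi_g) else z[t - 1]
      }
    }
    z
  })
}

#' Simulate one subject's regional time series
#'
#' @param config a [cohort_config()].
#' @param group group label.
#' @param subject_seed integer seed for this subject.
#' @param subject_id identifier stored on the result.
#' @return object of class `roi_timeseries` with fields `series`
#'   (`n_roi x M` matrix), `tr`, `group`, `subject_id`, `roi_labels`, and the
#'   ground-truth `state_seq`.
#' @export
generate_subject_timeseries <- function(config, group, subject_seed,
                                        subject_id = "s1") {
  m <- config$n_timepoints_by_group[[group]]
  z <- sample_state_sequence(m, config$states, group, subject_seed)
  chols <- lapply(config$states, function(s) {
    tryCatch(chol(s$covariance), error = function(e)
      stop("Cholesky factorization failed for state ", s$state_id))
  })
  series <- with_seed(derive_seed(subject_seed, 1), {
    noise <- matrix(rnorm(config$n_roi * m, sd = config$observation_noise_sd),
                    config$n_roi, m)
    base <- matrix(rnorm(config$n_roi * m), config$n_roi, m)
    out <- matrix(0, config$n_roi, m)
    for (s in seq_along(config$states)) {
      idx <- which(z == s)
      if (length(idx))
        out[, idx] <- crossprod(chols[[s]], base[, idx, drop = FALSE])
    }
    out + noise
  })
  roi_timeseries(series, tr = config$tr_by_group[[group]], group = group,
                 subject_id = subject_id, state_seq = z)
}

#' Construct a regional time-series object
#'
#' @param series numeric matrix, regions x time; must be finite.
#' @param tr repetition time in seconds.
#' @param group group label.
#' @param subject_id identifier.
#' @param roi_labels optional region labels.
#' @param state_seq optional ground-truth state sequence (simulation only).
#' @return object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(series, tr, group = NA_character_,
                           subject_id = NA_character_, roi_labels = NULL,
                           state_seq = NULL) {
  series <- as.matrix(series)
  if (!all(is.finite(series))) stop("series contains non-finite values")
  stopifnot(tr > 0)
  if (is.null(roi_labels)) roi_labels <- as.character(seq_len(nrow(series)))
  structure(list(series = series, tr = tr, group = group,
                 subject_id = subject_id, roi_labels = roi_labels,
                 state_seq = state_seq),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries %s group=%s: %d regions x %d time points, TR %.1f s>\n",
              x$subject_id, x$group, nrow(x$series), ncol(x$series), x$tr))
  invisible(x)
}

#' Simulate a full two-group cohort
#'
#' Generates every subject of both groups under `config`, with per-subject
#' seeds derived deterministically from `config$seed` so the cohort is fully
#' reproducible and subjects are independent streams.
#'
#' @param config a [cohort_config()].
#' @return object of class `dfc_cohort`: list with `subjects` (named list of
#'   `roi_timeseries`), `manifest` (data.frame: subject_id, group, tr, path),
#'   `config`, and `truth` (per-subject empirical state occupancy matrix).
#' @export
simulate_cohort <- function(config) {
  groups <- names(config$tr_by_group)
  subjects <- list()
  rows <- list()
  i <- 0L
  for (g in groups) {
    for (j in seq_len(config$n_subjects_per_group)) {
      i <- i + 1L
      sid <- sprintf("%s%02d", g, j)
      subjects[[sid]] <- generate_subject_timeseries(
        config, g, derive_seed(config$seed, i), subject_id = sid)
      rows[[i]] <- data.frame(subject_id = sid, group = g,
                              tr = config$tr_by_group[[g]],
                              path = NA_character_, stringsAsFactors = FALSE)
    }
  }
  n_states <- length(config$states)
  occ <- t(vapply(subjects, function(s)
    tabulate(s$state_seq, n_states) / length(s$state_seq),
    numeric(n_states)))
  colnames(occ) <- paste0("state", seq_len(n_states))
  structure(list(subjects = subjects, manifest = do.call(rbind, rows),
                 config = config, truth = occ),
            class = "dfc_cohort")
}

#' @export
print.dfc_cohort <- function(x, ...) {
  cat(sprintf("<dfc_cohort: %d subjects (%s), %d regions, %d latent states>\n",
              nrow(x$manifest),
              paste(sprintf("%s n=%d", names(table(x$manifest$group)),
                            as.integer(table(x$manifest$group))), collapse = ", "),
              x$config$n_roi, length(x$config$states)))
  invisible(x)
}

#' Write a cohort to disk as TSV files
#'
#' Writes one `series` TSV per subject (rows = regions, columns = time),
#' a manifest TSV (`subject_id`, `group`, `tr`, `path`) and a ground-truth
#' TSV of state ids per time point.
#'
#' @param cohort a `dfc_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  truth <- list()
  for (i in seq_len(nrow(man))) {
    sid <- man$subject_id[i]
    p <- file.path(dir, paste0(sid, "_series.tsv"))
    write.table(cohort$subjects[[sid]]$series, p, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    man$path[i] <- p
    zs <- cohort$subjects[[sid]]$state_seq
    if (!is.null(zs))
      truth[[sid]] <- data.frame(subject_id = sid,
                                 timepoint = seq_along(zs), state = zs)
  }
  man_path <- file.path(dir, "manifest.tsv")
  write.table(man, man_path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (length(truth))
    write.table(do.call(rbind, truth), file.path(dir, "truth_states.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(man_path)
}

#' Read a cohort from a manifest TSV
#'
#' @param manifest_path path to a manifest written by [write_cohort()] (or
#'   assembled by hand with columns subject_id, group, tr, path).
#' @return a `dfc_cohort` (without simulation truth or config).
#' @export
read_cohort <- function(manifest_path) {
  man <- read.table(manifest_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "tr", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  subjects <- list()
  for (i in seq_len(nrow(man))) {
    m <- as.matrix(read.table(man$path[i], sep = "\t", header = FALSE))
    subjects[[man$subject_id[i]]] <- roi_timeseries(
      m, tr = man$tr[i], group = man$group[i], subject_id = man$subject_id[i])
  }
  structure(list(subjects = subjects, manifest = man, config = NULL,
                 truth = NULL), class = "dfc_cohort")
}
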