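# Shared fixtures built in code: small cohorts, truth-based diagnostics,
# and a toy atlas with coordinates.

# A small planted-difference cohort; defaults sized for fast unit tests.
quick_cohort <- function(n_per_group = 6, n_roi = 30, seed = 1, ...) {
  simulate_cohort(cohort_config(n_subjects_per_group = n_per_group,
                                n_roi = n_roi, seed = seed, ...))
}

# Dominant true latent state for every WQCP sample of a fitted model
# (over the time points its segment's windows cover).
sample_dominant_states <- function(model, cohort) {
  n_states <- length(cohort$config$states)
  dom <- integer(nrow(model$samples))
  for (i in seq_len(nrow(model$samples))) {
    s <- model$samples[i, ]
    subj <- cohort$subjects[[s$subject_id]]
    w <- if (!is.null(model$w)) model$w else
      compute_window_length(subj$tr, model$duration_s)
    span <- s$start:(s$end + w - 1)
    dom[i] <- which.max(tabulate(subj$state_seq[span], n_states))
  }
  dom
}

# TRUE iff assigning each cluster its modal true state yields a bijection
# onto 1..n_states (every planted state recovered by exactly one cluster).
cluster_state_bijection <- function(labels, dom, n_states) {
  if (max(labels) != n_states) return(FALSE)
  tab <- table(factor(labels, levels = seq_len(n_states)),
               factor(dom, levels = seq_len(n_states)))
  modal <- apply(tab, 1, which.max)
  length(unique(modal)) == n_states
}

# Three-region atlas with coordinates, written to a temp TSV.
toy_atlas <- function() {
  path <- tempfile(fileext = ".tsv")
  at <- data.frame(index = 1:3, abbreviation = c("R1", "R2", "R3"),
                   description = paste("region", 1:3),
                   lobe = c("Frontal", "Frontal", "Occipital"),
                   x = c(0, 10, -10), y = c(0, 20, -20), z = c(5, 5, 5))
  write.table(at, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_atlas(path)
}
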