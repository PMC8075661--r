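## End-to-end pipeline: configuration, orchestration of every stage, and a
## JSON run report with artifacts.

#' Pipeline configuration
#'
#' Defaults reproduce the reference analysis settings: 36 s windows with
#' step 1, Davies-Bouldin K selection, significance numerators 0.0001 for
#' both the occupancy-ratio and edgewise tests, proportional densities
#' 0.10-0.40 (step 0.01), and visualization edge threshold 0.75.
#'
#' @param duration_s window duration in seconds.
#' @param w optional explicit window length (time points) for sensitivity
#'   runs.
#' @param step window step.
#' @param k fixed pattern count or `NULL` for Davies-Bouldin selection.
#' @param k_range candidate K values.
#' @param alpha_ratio_numerator,alpha_edge_numerator Bonferroni-style
#'   threshold numerators.
#' @param densities proportional-threshold grid for graph metrics.
#' @param viz_edge_threshold absolute-edge threshold for visualization
#'   export.
#' @param seed master seed for resampling.
#' @param resample_rates,resample_runs subject-resampling specification.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(duration_s = 36, w = NULL, step = 1,
                            k = NULL, k_range = 2:30,
                            alpha_ratio_numerator = 1e-4,
                            alpha_edge_numerator = 1e-4,
                            densities = seq(0.10, 0.40, by = 0.01),
                            viz_edge_threshold = 0.75,
                            seed = 1,
                            resample_rates = c(0.5, 0.9),
                            resample_runs = 4) {
  structure(list(duration_s = duration_s, w = w, step = step, k = k,
                 k_range = k_range,
                 alpha_ratio_numerator = alpha_ratio_numerator,
                 alpha_edge_numerator = alpha_edge_numerator,
                 densities = densities,
                 viz_edge_threshold = viz_edge_threshold,
                 seed = seed, resample_rates = resample_rates,
                 resample_runs = resample_runs),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' Configurations round-trip unchanged through serialization.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config`: the path, invisibly. `read_config`: the
#'   configuration.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, list())
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  # yaml flattens integer sequences to lists on some writers; normalize
  for (nm in c("k_range", "densities", "resample_rates"))
    cfg[[nm]] <- as.numeric(unlist(cfg[[nm]]))
  cfg$k_range <- as.integer(cfg$k_range)
  cfg
}

#' Run the full pattern-extraction pipeline
#'
#' Executes every stage over a cohort: model fit (windowed dFC,
#' segmentation, WQCP assembly, twice-clustering with optional K
#' selection), specific/general classification, pattern centroids, graph
#' metrics and critical regions on the specific pattern's group-A centroid,
#' edgewise group differences within each general pattern, and their
#' intersection. Artifacts (labels, ratios, classification, edge lists,
#' metric table, JSON report) are written under `out_dir` when given.
#'
#' @param cohort a `dfc_cohort`.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for artifacts.
#' @param atlas optional [load_atlas()] table for edge labeling.
#' @return object of class `dfcp_run`: list with `model`,
#'   `classification`, `ratios`, `centroids_by_group`, `critical`
#'   (per specific pattern), `edges` (per general pattern),
#'   `intersection`, `report`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         out_dir = NULL, atlas = NULL) {
  stopifnot(inherits(cohort, "dfc_cohort"), inherits(config, "pipeline_config"))
  stage <- "model fit"
  res <- tryCatch({
    model <- fit_dfcp(cohort, duration_s = config$duration_s, w = config$w,
                      step = config$step, k = config$k,
                      k_range = config$k_range)
    stage <- "classification"
    ratios <- occupancy_ratios(model)
    cls <- classify_dfcps(ratios, config$alpha_ratio_numerator)
    specific <- cls$dfcp[cls$specific]
    general <- cls$dfcp[!cls$specific]
    stage <- "centroids"
    cent_g <- dfcp_centroids(model, scope = "by_group")
    stage <- "graph metrics"
    groups <- sort(unique(model$samples$group))
    critical <- lapply(specific, function(kk) {
      cen <- cent_g[[kk]][[groups[1]]]
      if (cen$absent) return(NULL)
      mt <- graph_metric_table(cen$matrix, densities = config$densities)
      list(dfcp = kk, metrics = mt, rois = select_critical_rois(mt))
    })
    stage <- "edgewise differences"
    edges <- lapply(general, function(kk)
      edgewise_group_difference(model, kk, config$alpha_edge_numerator))
    names(edges) <- as.character(general)
    masks <- lapply(edges, function(e) if (is.null(e)) NULL else e$mask)
    intersection <- if (length(Filter(Negate(is.null), masks)))
      intersect_significant_edges(masks, atlas) else NULL
    list(model = model, ratios = ratios, classification = cls,
         centroids_by_group = cent_g, critical = critical, edges = edges,
         intersection = intersection)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  report <- list(
    k = res$model$k,
    n_samples = nrow(res$model$wqcp),
    n_subjects = length(unique(res$model$samples$subject_id)),
    n_roi = res$model$n_roi,
    specific_dfcps = I(res$classification$dfcp[res$classification$specific]),
    n_general = sum(!res$classification$specific),
    critical_rois = I(lapply(res$critical, function(cc)
      if (is.null(cc)) integer(0) else cc$rois$intersection)),
    intersection_edges = if (is.null(res$intersection)) list() else
      res$intersection$edges,
    config = unclass(config))
  res$report <- report
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(data.frame(sample = seq_along(res$model$labels),
                           res$model$samples, dfcp = res$model$labels),
                file.path(out_dir, "labels.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(data.frame(subject_id = rownames(res$ratios$ratios),
                           group = res$ratios$group, res$ratios$ratios),
                file.path(out_dir, "ratios.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(res$classification, file.path(out_dir, "classification.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(res$model$db_curve))
      write.table(data.frame(k = as.integer(names(res$model$db_curve)),
                             db = res$model$db_curve),
                  file.path(out_dir, "db_curve.csv"), sep = ",",
                  row.names = FALSE, quote = FALSE)
    for (nm in names(res$edges)) {
      e <- res$edges[[nm]]
      if (is.null(e)) next
      sig <- e$table[e$table$p < e$alpha, , drop = FALSE]
      write.table(sig, file.path(out_dir, paste0("edges_dfcp", nm, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(res) <- "dfcp_run"
  res
}

#' @export
print.dfcp_run <- function(x, ...) {
  cat(sprintf("<dfcp_run: K = %d; %d specific, %d general pattern(s)>\n",
              x$report$k, length(x$report$specific_dfcps),
              x$report$n_general))
  if (length(x$report$specific_dfcps))
    cat("  specific:", paste(x$report$specific_dfcps, collapse = " "), "\n")
  if (!is.null(x$intersection))
    cat("  intersection edges:", nrow(x$intersection$edges), "\n")
  invisible(x)
}
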