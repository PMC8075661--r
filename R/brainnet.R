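## BrainNet Viewer export: .node files are 6 whitespace-delimited columns
## (x, y, z, color group, size, label); .edge files are the full square
## connectivity matrix with sub-threshold values zeroed.

#' Export BrainNet Viewer node and edge files
#'
#' @param matrix square connectivity matrix (regions x regions), e.g. a
#'   pattern centroid.
#' @param atlas an [load_atlas()] table with coordinate columns `x`, `y`,
#'   `z` for every region used; missing coordinates are an error listing
#'   the offending regions.
#' @param path_prefix output prefix; writes `<prefix>.node` and
#'   `<prefix>.edge`.
#' @param node_size per-region size column (default: degree of the
#'   thresholded matrix; any numeric vector of length `n_roi`).
#' @param edge_threshold absolute-value threshold below which edges are
#'   zeroed in the .edge file (default 0.75).
#' @param color_group integer color group per region (default: `lobe`
#'   factor codes when present, else 1).
#' @return invisible character vector of the two file paths.
#' @export
export_brainnet_files <- function(matrix, atlas, path_prefix,
                                  node_size = NULL, edge_threshold = 0.75,
                                  color_group = NULL) {
  m <- as.matrix(matrix)
  n <- nrow(m)
  stopifnot(inherits(atlas, "atlas_table"), n == ncol(m))
  if (nrow(atlas) < n) stop("atlas has fewer regions than the matrix")
  at <- atlas[seq_len(n), ]
  if (!all(c("x", "y", "z") %in% names(at)))
    stop("atlas lacks coordinate columns x/y/z")
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad))
    stop("missing coordinates for region(s): ", paste(bad, collapse = ", "))
  edge <- m
  edge[abs(edge) < edge_threshold] <- 0
  if (is.null(node_size)) node_size <- rowSums(abs(edge) > 0)
  if (is.null(color_group))
    color_group <- if ("lobe" %in% names(at)) as.integer(factor(at$lobe))
      else rep(1L, n)
  node <- data.frame(x = at$x, y = at$y, z = at$z,
                     color = color_group, size = node_size,
                     label = gsub("\\s", "_", at$abbreviation))
  node_path <- paste0(path_prefix, ".node")
  edge_path <- paste0(path_prefix, ".edge")
  write.table(node, node_path, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  write.table(edge, edge_path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(c(node_path, edge_path))
}
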