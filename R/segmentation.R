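## Automatic segmentation of the dFC-strength time course into quasistable
## epochs and time-averaging of each epoch into a WQCP sample.
##
## Segmentation runs along TIME: consecutive windows whose strength profiles
## are similar belong to the same epoch; a window index is a segment point
## when the distance to its successor is a strict local maximum of the
## adjacent-distance curve.

#' Euclidean distances between adjacent strength profiles
#'
#' @param dfcs dFC-strength matrix (regions x windows) from
#'   [dfc_strength()].
#' @return numeric vector of length `n_windows - 1`; element i is the
#'   Euclidean distance between the profiles of windows i and i + 1.
#' @export
adjacent_distances <- function(dfcs) {
  dfcs <- as.matrix(dfcs)
  b <- ncol(dfcs)
  if (b < 2) stop("need at least 2 windows")
  sqrt(colSums((dfcs[, -1, drop = FALSE] - dfcs[, -b, drop = FALSE])^2))
}

#' Locate segment points as strict peaks of the distance curve
#'
#' Index i (1-based position in `d`) is selected iff
#' `d[i] > d[i - 1]` and `d[i] > d[i + 1]` (both strict); the first and last
#' distances can never be peaks, and plateaus yield no peak.
#'
#' @param d adjacent-distance vector from [adjacent_distances()].
#' @return integer vector of peak indices (possibly empty).
#' @export
detect_segment_points <- function(d) {
  l <- length(d)
  if (l < 3) return(integer(0))
  i <- 2:(l - 1)
  i[d[i] > d[i - 1] & d[i] > d[i + 1]]
}

#' Partition windows into segments at the given boundaries
#'
#' Segment point i ends a segment after window i: boundaries `{2, 5}` over 7
#' windows give segments `[1..2]`, `[3..5]`, `[6..7]` (1-based inclusive).
#'
#' @param n_windows total number of windows.
#' @param boundaries strictly increasing segment points in
#'   `1..n_windows - 1` (as produced by [detect_segment_points()]).
#' @return object of class `segment_set`: data.frame with columns `start`,
#'   `end` (1-based inclusive window indices) and `length`.
#' @export
build_segments <- function(n_windows, boundaries = integer(0)) {
  boundaries <- as.integer(boundaries)
  stopifnot(n_windows >= 1)
  if (length(boundaries)) {
    if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
    if (min(boundaries) < 1 || max(boundaries) >= n_windows)
      stop("boundary out of range [1, n_windows - 1]")
  }
  ends <- c(boundaries, n_windows)
  starts <- c(1L, boundaries + 1L)
  structure(data.frame(start = starts, end = ends,
                       length = ends - starts + 1L),
            class = c("segment_set", "data.frame"))
}

#' Time-average each segment into a WQCP sample
#'
#' The whole-brain quasistable connectome pattern (WQCP) of a segment is the
#' columnwise mean of the dFC-strength matrix over the segment's windows — a
#' single strength profile summarizing one quasistable epoch. The segment
#' length in windows is kept as the sample weight.
#'
#' @param dfcs dFC-strength matrix (regions x windows).
#' @param segments a [build_segments()] result (defaults to automatic
#'   segmentation of `dfcs`).
#' @param subject_id,group metadata copied onto every sample.
#' @return list with `vectors` (segments x regions matrix), `meta`
#'   (data.frame: subject_id, group, start, end, weight).
#' @export
compute_wqcps <- function(dfcs, segments = NULL,
                          subject_id = NA_character_, group = NA_character_) {
  dfcs <- as.matrix(dfcs)
  if (is.null(segments)) {
    d <- adjacent_distances(dfcs)
    segments <- build_segments(ncol(dfcs), detect_segment_points(d))
  }
  stopifnot(inherits(segments, "segment_set"))
  v <- t(vapply(seq_len(nrow(segments)), function(s) {
    rowMeans(dfcs[, segments$start[s]:segments$end[s], drop = FALSE])
  }, numeric(nrow(dfcs))))
  list(vectors = v,
       meta = data.frame(subject_id = subject_id, group = group,
                         start = segments$start, end = segments$end,
                         weight = segments$length, stringsAsFactors = FALSE))
}

#' Segment one subject end-to-end
#'
#' Convenience wrapper: windowed dFC, strength matrix, automatic
#' segmentation, WQCP samples, and the per-segment mean dFC matrices needed
#' later for pattern centroids.
#'
#' @param ts a [roi_timeseries()].
#' @param w window length in time points; default derived from the
#'   subject's TR via [compute_window_length()].
#' @param duration_s window duration in seconds used when `w` is `NULL`.
#' @param step window step.
#' @return list with `wqcp` (as [compute_wqcps()]), `segment_means` (list of
#'   per-segment mean dFC matrices), `segments`, `n_windows`, `w`.
#' @export
segment_subject <- function(ts, w = NULL, duration_s = 36, step = 1) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (is.null(w)) w <- compute_window_length(ts$tr, duration_s)
  tensor <- sliding_window_dfc(ts, w, step)
  dfcs <- dfc_strength(tensor)
  d <- adjacent_distances(dfcs)
  segments <- build_segments(ncol(dfcs), detect_segment_points(d))
  wq <- compute_wqcps(dfcs, segments, subject_id = ts$subject_id,
                      group = ts$group)
  n <- dim(tensor$arr)[1]
  flat <- matrix(tensor$arr, n * n)   # column b = vec of window b's matrix
  seg_means <- lapply(seq_len(nrow(segments)), function(s) {
    idx <- segments$start[s]:segments$end[s]
    matrix(rowMeans(flat[, idx, drop = FALSE]), n, n)
  })
  list(wqcp = wq, segment_means = seg_means, segments = segments,
       n_windows = dim(tensor$arr)[3], w = w)
}
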