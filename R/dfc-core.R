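## Sliding-window dynamic functional connectivity (dFC) and derived
## strength profiles. Correlations are raw Pearson r throughout; no Fisher
## z-transform is applied anywhere in the pipeline.

#' Motion-based exclusion decision
#'
#' Applies the rigid-body realignment-parameter screen: a subject is
#' excluded if any translation exceeds 1.5 mm in absolute value or any
#' rotation exceeds 1.5 degrees (strict inequalities; values exactly at the
#' limit are kept).
#'
#' @param motion_params numeric matrix or data.frame with 6 columns:
#'   translations x/y/z in mm, then rotations in degrees. May also be a file
#'   path to a whitespace-delimited 6-column realignment-parameter file.
#' @param translation_limit_mm exclusion threshold for translations.
#' @param rotation_limit_deg exclusion threshold for rotations.
#' @return list with `keep` (logical) and `reason` (string).
#' @export
qc_motion_exclusion <- function(motion_params, translation_limit_mm = 1.5,
                                rotation_limit_deg = 1.5) {
  if (is.character(motion_params)) {
    motion_params <- tryCatch(
      as.matrix(read.table(motion_params, header = FALSE)),
      error = function(e) stop("malformed motion file: ", conditionMessage(e)))
  }
  m <- as.matrix(motion_params)
  if (ncol(m) != 6) stop("motion parameters must have 6 columns, got ", ncol(m))
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("malformed motion parameters at line ", bad[1, 1])
  max_t <- max(abs(m[, 1:3]))
  max_r <- max(abs(m[, 4:6]))
  if (max_t > translation_limit_mm)
    return(list(keep = FALSE,
                reason = sprintf("translation %.3f mm > %.1f mm",
                                 max_t, translation_limit_mm)))
  if (max_r > rotation_limit_deg)
    return(list(keep = FALSE,
                reason = sprintf("rotation %.3f deg > %.1f deg",
                                 max_r, rotation_limit_deg)))
  list(keep = TRUE, reason = "within motion limits")
}

#' Discard initial volumes
#'
#' Removes the first `n_drop` time points (signal-equilibration scans) from
#' a regional time series.
#'
#' @param ts a [roi_timeseries()].
#' @param n_drop number of leading time points to remove (default 10).
#' @return the trimmed `roi_timeseries`.
#' @export
drop_initial_volumes <- function(ts, n_drop = 10) {
  stopifnot(inherits(ts, "roi_timeseries"), n_drop >= 0)
  m <- ncol(ts$series)
  if (m <= n_drop)
    stop("series has ", m, " time points; cannot drop ", n_drop)
  if (n_drop == 0) return(ts)
  ts$series <- ts$series[, (n_drop + 1):m, drop = FALSE]
  if (!is.null(ts$state_seq)) ts$state_seq <- ts$state_seq[(n_drop + 1):m]
  ts
}

#' Window length in time points from duration and TR
#'
#' `W = round(duration_s / tr_s)`; 36 s gives W = 12 at TR 3.0 s and W = 18
#' at TR 2.0 s. Fewer than 3 points would make windowed correlation
#' degenerate and is an error.
#'
#' @param tr_s repetition time, seconds.
#' @param duration_s window duration, seconds (default 36).
#' @return integer window length.
#' @export
compute_window_length <- function(tr_s, duration_s = 36) {
  stopifnot(tr_s > 0, duration_s > 0)
  w <- as.integer(round(duration_s / tr_s))
  if (w < 3) stop("window length ", w, " < 3 time points (TR ", tr_s,
                  " s, duration ", duration_s, " s)")
  w
}

# Correlation with zero-variance columns mapped to 0 rather than NA; used
# for both windowed and static connectivity. Warns once per call.
safe_cor <- function(x) {
  r <- suppressWarnings(cor(x))
  if (anyNA(r)) {
    warning("constant segment encountered; correlations involving it set to 0")
    r[!is.finite(r)] <- 0
  }
  r
}

#' Sliding-window dynamic functional connectivity tensor
#'
#' For window b (step `step`, covering `w` consecutive time points) computes
#' the Pearson correlation matrix of all region pairs over that window, with
#' the diagonal forced to zero. Zero-variance segments yield correlation 0
#' with a warning.
#'
#' @param ts a [roi_timeseries()] or a plain regions x time matrix.
#' @param w window length in time points (see [compute_window_length()]).
#' @param step window step in time points (default 1).
#' @return object of class `dfc_tensor`: list with `arr`
#'   (`n_roi x n_roi x n_windows` array), `subject_id`, `group`, `w`, `step`.
#' @export
sliding_window_dfc <- function(ts, w, step = 1) {
  if (inherits(ts, "roi_timeseries")) {
    series <- ts$series; sid <- ts$subject_id; grp <- ts$group
  } else {
    series <- as.matrix(ts); sid <- NA_character_; grp <- NA_character_
  }
  n <- nrow(series); m <- ncol(series)
  stopifnot(w >= 3, step >= 1)
  if (m < w) stop("series length ", m, " < window length ", w)
  starts <- seq(1, m - w + 1, by = step)
  arr <- array(0, dim = c(n, n, length(starts)))
  n_constant <- 0L
  withCallingHandlers(
    for (b in seq_along(starts)) {
      r <- safe_cor(t(series[, starts[b]:(starts[b] + w - 1), drop = FALSE]))
      diag(r) <- 0
      arr[, , b] <- r
    },
    warning = function(w_) {
      if (grepl("constant segment", conditionMessage(w_))) {
        n_constant <<- n_constant + 1L
        invokeRestart("muffleWarning")
      }
    })
  if (n_constant > 0)
    warning("constant segment in ", n_constant,
            " window(s); affected correlations set to 0")
  structure(list(arr = arr, subject_id = sid, group = grp,
                 w = as.integer(w), step = as.integer(step)),
            class = "dfc_tensor")
}

#' @export
print.dfc_tensor <- function(x, ...) {
  cat(sprintf("<dfc_tensor %s: %d x %d x %d windows (W=%d, step=%d)>\n",
              x$subject_id, dim(x$arr)[1], dim(x$arr)[2], dim(x$arr)[3],
              x$w, x$step))
  invisible(x)
}

#' dFC strength matrix from a tensor
#'
#' The strength of region i in window b is the sum of absolute dFC values
#' from i to every other region in that window (the diagonal is zero by
#' construction). Columns are ordered by window index, producing the
#' regions x windows dFC-strength (dFCS) matrix whose temporal structure is
#' later segmented into quasistable epochs.
#'
#' @param tensor a [sliding_window_dfc()] result.
#' @return numeric matrix, `n_roi x n_windows`, entries in
#'   `[0, n_roi - 1]`.
#' @export
dfc_strength <- function(tensor) {
  stopifnot(inherits(tensor, "dfc_tensor"))
  apply(abs(tensor$arr), 3, rowSums)
}

#' Static functional connectivity
#'
#' Pearson correlation over the entire series with zero diagonal — identical
#' conventions to a single window spanning all time points.
#'
#' @param ts a [roi_timeseries()] or regions x time matrix.
#' @return symmetric correlation matrix with zero diagonal.
#' @export
static_fc <- function(ts) {
  series <- if (inherits(ts, "roi_timeseries")) ts$series else as.matrix(ts)
  if (ncol(series) < 3) stop("need at least 3 time points for static FC")
  r <- safe_cor(t(series))
  diag(r) <- 0
  r
}
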