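# Banded Dynamic Time Warping core.
#
# All functions take plain numeric vectors; indices in the documentation and
# in returned paths are 1-based, matching the usual statement of the DTW
# recurrence: DTW(i, j) = (x1(i) - x2(j))^2 + min over the predecessors
# (i-1, j-1), (i-1, j), (i, j-1), with the obvious first-row/first-column
# edge cases and DTW(1, 1) = (x1(1) - x2(1))^2. The Sakoe-Chiba band
# restricts computation to |i - j| <= w.

#' Convert a warping window from seconds to samples
#'
#' The warping window (and the maximal lag of the cross-correlation
#' baseline) is specified in seconds and converted to a sample count using
#' the sampling interval `tr`. Rounding is half-away-from-zero, so e.g.
#' 100 s at a 1.77 s sampling interval gives 56 samples.
#'
#' @param seconds Nonnegative window length in seconds.
#' @param tr Sampling interval (repetition time) in seconds; must be > 0.
#' @return Integer number of samples (>= 0).
#' @examples
#' window_to_samples(100, 2)  # 50
#' window_to_samples(4, 2)    # 2
#' @export
window_to_samples <- function(seconds, tr) {
  check_tr(tr)
  if (!is.numeric(seconds) || length(seconds) != 1L || !is.finite(seconds) ||
      seconds < 0)
    stop("`seconds` must be a single nonnegative number")
  x <- seconds / tr
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

check_band <- function(l1, l2, w) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0)
    stop("warping window `w` must be a single nonnegative integer (samples)")
  w <- as.integer(w)
  if (w < abs(l1 - l2))
    stop(sprintf(paste0("infeasible band: w = %d samples cannot connect ",
                        "series of lengths %d and %d (need w >= %d)"),
                 w, l1, l2, abs(l1 - l2)))
  w
}

#' Banded DTW accumulated-cost matrix
#'
#' Fills the l1-by-l2 accumulated-cost matrix with squared-difference local
#' costs, restricted to the Sakoe-Chiba band `|i - j| <= w`. Entries outside
#' the band are `Inf` (treated as unavailable by the recurrence minimum).
#'
#' @param x1,x2 Numeric time series (rows of the matrix follow `x1`).
#' @param w Warping window in samples. Must satisfy
#'   `w >= abs(length(x1) - length(x2))` so the (l1, l2) corner is reachable.
#' @return A numeric matrix of accumulated costs; `Inf` outside the band.
#' @seealso [dtw_distance()], [warping_path()]
#' @export
dtw_matrix <- function(x1, x2, w = max(length(x1), length(x2))) {
  check_series(x1)
  check_series(x2)
  w <- check_band(length(x1), length(x2), w)
  m <- .dtw_cost_matrix_cpp(as.double(x1), as.double(x2), w)
  attr(m, "band") <- w
  m
}

#' Banded DTW distance
#'
#' The DTW distance is the square root of the (l1, l2) corner entry of the
#' accumulated-cost matrix built from squared sample differences within the
#' Sakoe-Chiba band. It is symmetric in its arguments, zero for identical
#' series, and non-increasing in `w`. With `w = 0` (and equal lengths) it
#' reduces to the Euclidean distance of the two series.
#'
#' DTW distances grow with series length; `normalize_by_length` divides the
#' distance by the number of time points so runs of different durations can
#' be compared.
#'
#' @inheritParams dtw_matrix
#' @param normalize_by_length Divide the distance by the number of time
#'   points (the larger of the two lengths). Default `FALSE`.
#' @return Nonnegative scalar distance.
#' @examples
#' dtw_distance(c(0, 1, 0), c(0, 0, 1))            # 1
#' dtw_distance(c(0, 0, 1, 0, 0), c(0, 1, 0, 0, 0), w = 1)  # 0
#' @export
dtw_distance <- function(x1, x2, w = max(length(x1), length(x2)),
                         normalize_by_length = FALSE) {
  check_series(x1)
  check_series(x2)
  w <- check_band(length(x1), length(x2), w)
  d <- sqrt(.dtw_corner_cpp(as.double(x1), as.double(x2), w))
  if (normalize_by_length) d <- d / max(length(x1), length(x2))
  d
}

#' Optimal warping path by backtracking
#'
#' Starting from the (l1, l2) corner, repeatedly steps to the in-band
#' predecessor with the smallest accumulated cost until (1, 1) is reached.
#' Ties are broken deterministically: diagonal first, then vertical
#' (i - 1, j), then horizontal (i, j - 1).
#'
#' @param m Accumulated-cost matrix from [dtw_matrix()] (must be complete to
#'   the corner, i.e. built with a feasible band).
#' @return Integer matrix with columns `i`, `j`: the matched index pairs in
#'   forward order from (1, 1) to (l1, l2).
#' @export
warping_path <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("`m` must be a numeric accumulated-cost matrix")
  l1 <- nrow(m)
  l2 <- ncol(m)
  if (!is.finite(m[l1, l2]))
    stop("corner entry is not finite; the band did not reach (l1, l2)")
  path <- matrix(NA_integer_, l1 + l2, 2L)
  i <- l1
  j <- l2
  k <- 0L
  repeat {
    k <- k + 1L
    path[k, ] <- c(i, j)
    if (i == 1L && j == 1L) break
    if (i == 1L) {
      j <- j - 1L
    } else if (j == 1L) {
      i <- i - 1L
    } else {
      cand <- c(m[i - 1L, j - 1L], m[i - 1L, j], m[i, j - 1L])
      pick <- which.min(cand)  # first minimum: diagonal > vertical > horiz.
      if (pick == 1L) { i <- i - 1L; j <- j - 1L }
      else if (pick == 2L) i <- i - 1L
      else j <- j - 1L
    }
  }
  path <- path[k:1, , drop = FALSE]
  colnames(path) <- c("i", "j")
  path
}

#' Per-step lag profile of a warping path
#'
#' Reads the warping path's deviation from the main diagonal as a time lag:
#' `(i - j) * tr` seconds for each matched pair. A diagonal path gives all
#' zeros; a constant k-sample shift shows as a plateau at `k * tr`. Intended
#' as a diagnostic of the delay structure between two series.
#'
#' @param path Path matrix from [warping_path()].
#' @param tr Sampling interval in seconds.
#' @return Numeric vector of lags in seconds, one per path step.
#' @export
path_lag_profile <- function(path, tr) {
  check_tr(tr)
  if (!is.matrix(path) || ncol(path) != 2L)
    stop("`path` must be a two-column (i, j) matrix")
  (path[, 1L] - path[, 2L]) * tr
}

#' Full DTW result (distance, path, matrix)
#'
#' Convenience wrapper bundling [dtw_matrix()], [dtw_distance()] and
#' [warping_path()] into one object.
#'
#' @inheritParams dtw_matrix
#' @param keep_matrix Retain the accumulated-cost matrix in the result.
#' @return An object of class `dtw_result`: list with `distance`, `path`,
#'   `band` and optionally `matrix`.
#' @export
dtw_align <- function(x1, x2, w = max(length(x1), length(x2)),
                      keep_matrix = FALSE) {
  m <- dtw_matrix(x1, x2, w)
  res <- list(distance = sqrt(m[nrow(m), ncol(m)]),
              path = warping_path(m),
              band = attr(m, "band"))
  if (keep_matrix) res$matrix <- m
  class(res) <- "dtw_result"
  res
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("DTW alignment: distance %.4f, band w = %d samples, path length %d\n",
              x$distance, x$band, nrow(x$path)))
  invisible(x)
}

#' Serialize a DTW result to JSON
#'
#' @param x A `dtw_result`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
dtw_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "dtw_result"))
  obj <- list(distance = x$distance, band = x$band,
              path = unname(apply(x$path, 1L, as.list)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
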