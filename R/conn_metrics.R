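# Connectivity metrics on prepared series: zero-lag Pearson correlation,
# maximal-lag cross-correlation, DTW distance, and the distance-to-
# similarity transform that makes DTW values comparable to correlations
# (negate, then demean over the analysis unit).

metric_value <- function(metric, value, lag_seconds = 0) {
  structure(list(metric = metric, value = value, lag_seconds = lag_seconds),
            class = "metric_value")
}

#' @export
print.metric_value <- function(x, ...) {
  cat(sprintf("%s: %.4f", x$metric, x$value))
  if (x$metric == "xcorr") cat(sprintf(" (lag %.2f s)", x$lag_seconds))
  cat("\n")
  invisible(x)
}

#' Zero-lag Pearson correlation
#'
#' @param x1,x2 Numeric series of equal length, neither constant.
#' @return A `metric_value` with `metric = "correlation"`.
#' @export
pearson <- function(x1, x2) {
  check_series(x1)
  check_series(x2)
  if (length(x1) != length(x2)) stop("series lengths differ")
  if (sd_pop(x1) == 0 || sd_pop(x2) == 0)
    stop("degenerate input: constant series has no correlation")
  metric_value("correlation", cor(x1, x2))
}

#' Maximal-lag cross-correlation
#'
#' Computes the Pearson correlation of the overlapping samples at every
#' integer lag in `[-max_lag, +max_lag]` (the overlap is renormalized at
#' each lag, so every coefficient lies in `[-1, 1]`; no zero padding) and
#' returns the coefficient with the largest absolute magnitude, sign
#' preserved, together with its lag in seconds. A signed value is kept
#' because anticorrelated pairs should report their negative maximal-lag
#' coefficient rather than a competing positive one. Ties go to the
#' smaller `|lag|`, then to the positive lag. A positive lag means `x2`
#' trails `x1` by that many seconds.
#'
#' @param x1,x2 Numeric series of equal length.
#' @param max_lag_s Maximal lag, seconds.
#' @param tr Sampling interval, seconds.
#' @return A `metric_value` with `metric = "xcorr"` and `lag_seconds` set.
#' @export
max_lag_xcorr <- function(x1, x2, max_lag_s, tr) {
  check_series(x1)
  check_series(x2)
  check_tr(tr)
  n <- length(x1)
  if (length(x2) != n) stop("series lengths differ")
  L <- window_to_samples(max_lag_s, tr)
  if (L >= n) stop("`max_lag_s` must be shorter than the series")
  # visit lags as 0, +1, -1, +2, -2, ... and keep strictly larger |r|,
  # which realizes the tie-break (smaller |lag|, then positive lag).
  lag_order <- c(0L, as.vector(rbind(seq_len(L), -seq_len(L))))
  best_r <- NA_real_
  best_lag <- 0L
  skipped <- 0L
  for (k in lag_order) {
    if (k >= 0L) {
      a <- x1[seq_len(n - k)]
      b <- x2[seq_len(n - k) + k]
    } else {
      a <- x1[seq_len(n + k) - k]
      b <- x2[seq_len(n + k)]
    }
    if (length(a) < 3L) { skipped <- skipped + 1L; next }
    if (sd_pop(a) == 0 || sd_pop(b) == 0) { skipped <- skipped + 1L; next }
    r <- cor(a, b)
    if (is.na(best_r) || abs(r) > abs(best_r)) {
      best_r <- r
      best_lag <- k
    }
  }
  if (skipped > 0L)
    warning(sprintf("%d lag(s) skipped (overlap too short or constant)",
                    skipped))
  if (is.na(best_r)) stop("no usable lag")
  metric_value("xcorr", best_r, lag_seconds = best_lag * tr)
}

#' DTW distance between z-scored series
#'
#' Evaluates [dtw_distance()] after z-scoring both inputs (z-scoring is
#' idempotent, so already-normalized series are unchanged). This makes the
#' metric invariant to affine rescaling of either input, in line with
#' correlation-based metrics which normalize by definition.
#'
#' @param x1,x2 Numeric series.
#' @param window_s Warping window in seconds.
#' @param tr Sampling interval in seconds.
#' @param normalize_by_length Passed to [dtw_distance()].
#' @return A `metric_value` with `metric = "dtw"` (a distance: small means
#'   strongly connected).
#' @export
dtw_metric <- function(x1, x2, window_s, tr, normalize_by_length = FALSE) {
  check_tr(tr)
  w <- window_to_samples(window_s, tr)
  metric_value("dtw", dtw_distance(zscore(x1), zscore(x2), w,
                                   normalize_by_length = normalize_by_length))
}

#' Transform DTW distances into similarities
#'
#' Over one analysis unit (all voxels of a seed map, or all pairs of a
#' connectivity matrix) DTW distances are multiplied by -1 and demeaned:
#' `similarity_i = mean(d) - d_i`. Unconnected pairs then scatter around
#' zero (approximately normally, which licenses one-sample t statistics),
#' and larger similarity means stronger connection. The map is
#' order-reversing and affine, so the smallest distance becomes the
#' largest similarity.
#'
#' @param distances Numeric vector of at least two DTW distances.
#' @param unit Which analysis unit the values come from: `"seed-map"` or
#'   `"matrix"`. Stored for bookkeeping.
#' @return An object of class `similarity_set`: list with `raw_distances`,
#'   `similarities` (mean exactly zero) and `unit`.
#' @export
to_similarity <- function(distances, unit = c("seed-map", "matrix")) {
  unit <- match.arg(unit)
  if (!is.numeric(distances) || length(distances) < 2L)
    stop("need at least two distance values to demean")
  if (!all(is.finite(distances))) stop("distances must be finite")
  structure(list(raw_distances = distances,
                 similarities = mean(distances) - distances,
                 unit = unit),
            class = "similarity_set")
}

# Uniform internal dispatcher used by seed maps / matrices: returns the
# scalar metric value (and lag for xcorr) for one pair.
eval_metric <- function(x1, x2, metric, tr, window_s = 100,
                        max_lag_s = window_s) {
  switch(metric,
         correlation = pearson(x1, x2),
         xcorr = max_lag_xcorr(x1, x2, max_lag_s, tr),
         dtw = dtw_metric(x1, x2, window_s, tr),
         stop(sprintf("unknown metric '%s'", metric)))
}
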