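# Whole-brain connectivity products: seed-based maps over masked voxels
# and ROI-by-ROI connectivity matrices with upper-triangle feature vectors.

# Extract a voxel-by-time matrix (and voxel coordinates) from a 4D array
# restricted to a 3D logical mask.
mask_series <- function(bold, mask) {
  stopifnot(is.array(bold), length(dim(bold)) == 4L)
  d <- dim(bold)
  mask <- array(as.logical(mask), d[1:3])
  vox <- which(mask)
  mat <- matrix(bold, prod(d[1:3]), d[4L])[vox, , drop = FALSE]
  list(series = mat, voxels = arrayInd(vox, d[1:3]), index = vox)
}

# Vectorized per-lag correlations of one reference series against rows of
# a matrix; returns the signed maximal-|r| coefficient and its lag for
# every row (same selection rule as max_lag_xcorr).
xcorr_rows <- function(ref, M, L) {
  n <- length(ref)
  lag_order <- if (L > 0L) c(0L, as.vector(rbind(seq_len(L), -seq_len(L))))
               else 0L
  best_r <- rep(NA_real_, nrow(M))
  best_lag <- rep(0L, nrow(M))
  for (k in lag_order) {
    if (k >= 0L) { ia <- seq_len(n - k); ib <- ia + k }
    else { ib <- seq_len(n + k); ia <- ib - k }
    if (length(ia) < 3L) next
    a <- ref[ia]
    B <- M[, ib, drop = FALSE]
    a <- a - mean(a)
    B <- B - rowMeans(B)
    den <- sqrt(sum(a^2) * rowSums(B^2))
    r <- as.vector(B %*% a) / den
    r[!is.finite(r)] <- NA_real_
    upd <- !is.na(r) & (is.na(best_r) | abs(r) > abs(best_r))
    best_r[upd] <- r[upd]
    best_lag[upd] <- k
  }
  list(r = best_r, lag = best_lag)
}

#' Seed-based connectivity map
#'
#' Evaluates one connectivity metric between the time course of a seed
#' voxel and the time course of every voxel in the inclusion mask. The
#' input data must already be prepared (nuisance regression and band-pass
#' filtering applied); series are z-scored here before metric evaluation.
#' For DTW the map additionally carries the distance-to-similarity
#' transform computed across the map's voxels ([to_similarity()]), with
#' the raw distances retained for reanalysis.
#'
#' @param bold 4D array (x, y, z, t) of prepared BOLD data.
#' @param mask 3D logical array: voxels to include.
#' @param seed Integer vector `c(x, y, z)`: seed voxel coordinates
#'   (1-based, inside the mask), or a single linear voxel index.
#' @param metric `"correlation"`, `"xcorr"` or `"dtw"`.
#' @param tr Sampling interval, seconds.
#' @param window_s DTW warping window, seconds. Default 100.
#' @param max_lag_s Maximal cross-correlation lag, seconds. Defaults to
#'   `window_s` so both lag-aware metrics search the same range.
#' @return An object of class `conn_map`: list with `values` (per mask
#'   voxel; DTW similarity for `metric = "dtw"`), `raw` (DTW distances, or
#'   `NULL`), `lag_s` (xcorr lags, or `NULL`), `voxels` (n-by-3 index
#'   matrix), `seed`, `metric`, `params`, `dim`.
#' @export
seed_map <- function(bold, mask, seed, metric = c("correlation", "xcorr",
                                                  "dtw"),
                     tr, window_s = 100, max_lag_s = window_s) {
  metric <- match.arg(metric)
  check_tr(tr)
  ms <- mask_series(bold, mask)
  d <- dim(bold)
  if (length(seed) == 3L) {
    seed_idx <- seed[1L] + (seed[2L] - 1L) * d[1L] +
      (seed[3L] - 1L) * d[1L] * d[2L]
  } else if (length(seed) == 1L) {
    seed_idx <- seed
  } else stop("`seed` must be c(x, y, z) or a single linear index")
  pos <- match(seed_idx, ms$index)
  if (is.na(pos)) stop("seed voxel lies outside the mask")

  Z <- t(apply(ms$series, 1L, zscore))
  sz <- Z[pos, ]
  raw <- NULL
  lag_s <- NULL
  if (metric == "correlation") {
    values <- as.vector((Z %*% sz) / length(sz))
  } else if (metric == "xcorr") {
    L <- window_to_samples(max_lag_s, tr)
    xc <- xcorr_rows(sz, Z, L)
    values <- xc$r
    lag_s <- xc$lag * tr
  } else {
    w <- window_to_samples(window_s, tr)
    raw <- sqrt(.dtw_corner_many_cpp(sz, Z, w))
    values <- to_similarity(raw, unit = "seed-map")$similarities
  }
  structure(list(values = values, raw = raw, lag_s = lag_s,
                 voxels = ms$voxels, index = ms$index, seed = seed,
                 metric = metric,
                 params = list(tr = tr, window_s = window_s,
                               max_lag_s = max_lag_s),
                 dim = d[1:3]),
            class = "conn_map")
}

#' Render a connectivity map as a 3D volume
#'
#' @param x A `conn_map`.
#' @param what `"values"` (default) or `"raw"` (DTW distances).
#' @return 3D array with `NA` outside the mask.
#' @export
map_volume <- function(x, what = c("values", "raw")) {
  what <- match.arg(what)
  v <- x[[what]]
  if (is.null(v)) stop(sprintf("map has no '%s' component", what))
  vol <- array(NA_real_, x$dim)
  vol[x$index] <- v
  vol
}

#' ROI mean time series from an atlas
#'
#' For every positive integer label of the atlas (ascending order), the
#' unweighted mean time course over the member voxels is extracted and
#' z-scored. Labels without voxels are excluded with a warning.
#'
#' @param bold 4D array (x, y, z, t).
#' @param atlas 3D integer-label array on the same grid (0 = outside).
#' @param labels Labels to extract; defaults to all positive labels
#'   present.
#' @return Time-by-ROI numeric matrix with labels as column names.
#' @export
roi_timeseries <- function(bold, atlas, labels = NULL) {
  stopifnot(is.array(bold), length(dim(bold)) == 4L)
  d <- dim(bold)
  if (!all(dim(atlas) == d[1:3]))
    stop("atlas grid does not match the data grid")
  present <- sort(unique(as.integer(atlas[atlas > 0])))
  if (is.null(labels)) labels <- present
  labels <- sort(as.integer(labels))
  missing <- setdiff(labels, present)
  if (length(missing) > 0L) {
    warning("excluding empty label(s): ", paste(missing, collapse = ", "))
    labels <- intersect(labels, present)
  }
  flat <- matrix(bold, prod(d[1:3]), d[4L])
  out <- vapply(labels, function(lb)
    zscore(colMeans(flat[which(atlas == lb), , drop = FALSE])),
    numeric(d[4L]))
  colnames(out) <- labels
  out
}

#' ROI-by-ROI connectivity matrix
#'
#' Evaluates a metric on every unordered pair of series (computed once per
#' pair, so the matrix is symmetric by construction). The diagonal holds
#' the metric's self-value (correlation 1, DTW distance 0). For DTW the
#' matrix of raw distances is kept and a similarity matrix (demeaned over
#' the upper-triangle pairs, [to_similarity()] with `unit = "matrix"`) is
#' attached.
#'
#' @param series Time-by-ROI numeric matrix (>= 2 columns), e.g. from
#'   [roi_timeseries()].
#' @param metric `"correlation"`, `"xcorr"` or `"dtw"`.
#' @param tr Sampling interval, seconds.
#' @param window_s,max_lag_s See [seed_map()].
#' @return An object of class `conn_matrix`: list with `values` (symmetric
#'   matrix; raw distances for DTW), `similarity` (DTW only), `labels`,
#'   `metric`, `params`.
#' @export
connectivity_matrix <- function(series, metric = c("correlation", "xcorr",
                                                   "dtw"),
                                tr, window_s = 100, max_lag_s = window_s) {
  metric <- match.arg(metric)
  check_tr(tr)
  series <- as.matrix(series)
  n <- ncol(series)
  if (n < 2L) stop("need at least two series")
  labels <- colnames(series)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  Z <- apply(series, 2L, zscore)
  self <- if (metric == "dtw") 0 else 1
  m <- diag(self, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- eval_metric(Z[, i], Z[, j], metric, tr, window_s, max_lag_s)$value
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  dimnames(m) <- list(labels, labels)
  sim <- NULL
  if (metric == "dtw") {
    ut <- upper_tri_rowmajor(m)
    s <- to_similarity(ut, unit = "matrix")$similarities
    sim <- features_to_matrix(s, self = 0)
    dimnames(sim) <- dimnames(m)
  }
  structure(list(values = m, similarity = sim, labels = labels,
                 metric = metric,
                 params = list(tr = tr, window_s = window_s,
                               max_lag_s = max_lag_s)),
            class = "conn_matrix")
}

# Strictly-upper-triangle values in row-major order: (1,2), (1,3), ...,
# (1,n), (2,3), ...
upper_tri_rowmajor <- function(m) {
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Vectorize a connectivity matrix into pairwise features
#'
#' Returns the strictly-upper-triangle values in row-major order; for an
#' n-ROI matrix the feature vector has length `n * (n - 1) / 2` (e.g. 90
#' ROIs give 4005 features). DTW matrices pass through the similarity
#' transform (demeaned over the matrix's pairs) before vectorization. The
#' operation is invertible given n ([features_to_matrix()]).
#'
#' @param m A `conn_matrix` object, or a plain symmetric matrix.
#' @param tol Symmetry tolerance for plain matrices. Default 1e-8.
#' @return Named numeric vector of pair features (`"i_j"` names).
#' @export
matrix_to_features <- function(m, tol = 1e-8) {
  if (inherits(m, "conn_matrix")) {
    vals <- if (m$metric == "dtw") m$similarity else m$values
    labels <- m$labels
  } else {
    vals <- m
    labels <- rownames(m)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  }
  if (!is.matrix(vals) || nrow(vals) != ncol(vals))
    stop("`m` must be square")
  if (max(abs(vals - t(vals))) > tol)
    stop("matrix is asymmetric beyond tolerance")
  n <- nrow(vals)
  out <- upper_tri_rowmajor(vals)
  pairs <- which(upper.tri(vals), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  names(out) <- paste(labels[pairs[, 1L]], labels[pairs[, 2L]], sep = "_")
  out
}

#' Rebuild a symmetric matrix from an upper-triangle feature vector
#'
#' Inverse of [matrix_to_features()] (row-major strictly-upper-triangle
#' ordering).
#'
#' @param features Numeric vector of length `n * (n - 1) / 2`.
#' @param self Diagonal value. Default 1.
#' @return Symmetric n-by-n matrix.
#' @export
features_to_matrix <- function(features, self = 1) {
  p <- length(features)
  n <- (1 + sqrt(1 + 8 * p)) / 2
  if (abs(n - round(n)) > 1e-9)
    stop("feature length is not n * (n - 1) / 2 for integer n")
  n <- as.integer(round(n))
  m <- diag(self, n)
  tm <- t(m)
  tm[lower.tri(tm)] <- features
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}
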