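# Signal conditioning chain for resting-state BOLD series:
# nuisance regression (optionally including the global signal) strictly
# before band-pass filtering, then z-normalization. The band-pass is the
# combination used throughout: a DCT-basis high-pass (regressor set of
# cosines, default order 9) followed by a bidirectional 12th-order
# Butterworth low-pass at 0.08 Hz.

#' Band-pass filter specification
#'
#' @param highpass_order Number of DCT basis functions regressed out by the
#'   high-pass step (the constant term is extra). Default 9, which for a
#'   600 s run corresponds to a cutoff of order/(2T) = 0.0075 Hz, i.e. the
#'   conventional ~0.009-0.01 Hz high-pass of resting-state studies.
#' @param lowpass_hz Low-pass cutoff in Hz. Default 0.08.
#' @param lowpass_order Butterworth design order. Default 12. Applied
#'   forward-backward, so the effective magnitude roll-off doubles.
#' @param bidirectional Apply the low-pass forward and backward (zero
#'   phase). Default `TRUE`.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(highpass_order = 9L, lowpass_hz = 0.08,
                        lowpass_order = 12L, bidirectional = TRUE) {
  stopifnot(highpass_order >= 1L, lowpass_order >= 1L, lowpass_hz > 0)
  structure(list(highpass_order = as.integer(highpass_order),
                 lowpass_hz = lowpass_hz,
                 lowpass_order = as.integer(lowpass_order),
                 bidirectional = isTRUE(bidirectional)),
            class = "filter_spec")
}

#' DCT-basis high-pass filter
#'
#' Regresses the series on a DCT-II cosine basis of the given order (plus a
#' constant term) and returns the residual. Basis function k is
#' `cos(pi * k * (t + 0.5) / N)` for `t = 0..N-1`; the highest basis
#' frequency is `order / (2 * N * tr)` Hz, so slower components are removed
#' and faster ones pass through. The residual has mean (approximately) zero.
#'
#' @param x Numeric time series.
#' @param order Number of cosine basis functions (the constant is extra).
#'   Must be smaller than `length(x)`.
#' @return Filtered series of the same length.
#' @export
dct_highpass <- function(x, order = 9L) {
  check_series(x)
  n <- length(x)
  order <- as.integer(order)
  if (order < 1L || order >= n)
    stop("`order` must satisfy 1 <= order < length(x)")
  t0 <- seq_len(n) - 0.5
  basis <- vapply(seq_len(order),
                  function(k) cos(pi * k * t0 / n),
                  numeric(n))
  lm.fit(cbind(1, basis), x)$residuals
}

# Steady-state initial conditions of the direct form II transposed
# recursion for a unit-level input (scipy lfilter_zi convention).
iir_steady_state <- function(b, a) {
  n <- max(length(a), length(b)) - 1L
  bb <- c(b, numeric(n + 1L - length(b)))
  aa <- c(a, numeric(n + 1L - length(a)))
  comp <- matrix(0, n, n)
  comp[1L, ] <- -aa[2:(n + 1L)]
  if (n > 1L) comp[cbind(2:n, 1:(n - 1L))] <- 1
  solve(diag(n) - t(comp), bb[2:(n + 1L)] - aa[2:(n + 1L)] * bb[1L])
}

# Zero-phase filtering: odd-extension padding at both ends, forward pass,
# reversed backward pass, both started from steady state scaled by the
# first sample. Matches the usual filtfilt convention with pad length
# 3 * (filter order + 1), capped at length(x) - 1.
filtfilt_zp <- function(b, a, x) {
  n <- length(x)
  zi <- iir_steady_state(b, a)
  npad <- min(3L * (max(length(a), length(b)) - 1L + 1L), n - 1L)
  ext <- c(2 * x[1L] - x[(npad + 1L):2L], x,
           2 * x[n] - x[(n - 1L):(n - npad)])
  y <- .iir_filter_cpp(b, a, ext, zi * ext[1L])
  y <- rev(y)
  y <- .iir_filter_cpp(b, a, y, zi * y[1L])
  y <- rev(y)
  y[(npad + 1L):(npad + n)]
}

#' Butterworth low-pass filter (zero phase)
#'
#' Low-pass filters the series with a Butterworth IIR design at the cutoff
#' given in the spec, applied bidirectionally (forward and backward) so the
#' phase response is zero and the DC gain is exactly one. Coefficients come
#' from [signal::butter()]; the forward-backward application uses
#' odd-extension padding with steady-state initial conditions to suppress
#' edge transients.
#'
#' @param x Numeric time series.
#' @param tr Sampling interval in seconds.
#' @param spec A [filter_spec()].
#' @return Filtered series of the same length.
#' @export
butter_lowpass <- function(x, tr, spec = filter_spec()) {
  check_series(x)
  check_tr(tr)
  stopifnot(inherits(spec, "filter_spec"))
  n <- length(x)
  if (n < 3L * spec$lowpass_order)
    stop(sprintf("series too short for stable filtering: need >= %d samples",
                 3L * spec$lowpass_order))
  nyq <- 1 / (2 * tr)
  if (spec$lowpass_hz >= nyq)
    stop(sprintf("low-pass cutoff %.4f Hz is at or above Nyquist %.4f Hz",
                 spec$lowpass_hz, nyq))
  bf <- signal::butter(spec$lowpass_order, spec$lowpass_hz / nyq,
                       type = "low")
  if (spec$bidirectional) {
    filtfilt_zp(bf$b, bf$a, x)
  } else {
    zi <- iir_steady_state(bf$b, bf$a)
    .iir_filter_cpp(bf$b, bf$a, x, zi * x[1L])
  }
}

#' Band-pass filter a series (DCT high-pass then Butterworth low-pass)
#'
#' Applies [dct_highpass()] followed by [butter_lowpass()], in that order.
#' With the defaults this retains roughly the 0.009-0.08 Hz band used in
#' resting-state functional connectivity.
#'
#' @inheritParams butter_lowpass
#' @return Filtered series of the same length.
#' @export
bandpass <- function(x, tr, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  butter_lowpass(dct_highpass(x, spec$highpass_order), tr, spec)
}

#' Nuisance regression
#'
#' Returns the residual of an ordinary least-squares regression of the
#' series on the confound columns plus an intercept. The residual is
#' orthogonal to every confound. A rank-deficient confound matrix triggers
#' a warning and a pseudoinverse solution.
#'
#' @param x Numeric time series.
#' @param confounds Matrix or data frame of confound series (one column
#'   each), same number of rows as `length(x)`.
#' @return Residual series of the same length.
#' @export
nuisance_regress <- function(x, confounds) {
  check_series(x)
  C <- as.matrix(confounds)
  if (nrow(C) != length(x))
    stop("confound length does not match the series")
  if (ncol(C) < 1L) stop("need at least one confound column")
  X <- cbind(1, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient confound matrix; using pseudoinverse solution")
    beta <- MASS::ginv(X) %*% x
    return(as.numeric(x - X %*% beta))
  }
  as.numeric(qr.resid(qrX, x))
}

#' Extract a nuisance confound set from voxel data
#'
#' Builds the standard confound set: 6 motion parameters, mean white-matter
#' (WM) and mean cerebrospinal-fluid (CSF) series, the first five principal
#' component series of the WM voxels and of the CSF voxels (computed on
#' demeaned voxel series, ordered by explained variance), and optionally
#' the global signal (unweighted mean over brain-mask voxels). With the
#' global signal the set has 6 + 1 + 1 + 5 + 5 + 1 = 19 columns.
#'
#' @param data Voxel-by-time numeric matrix, or a 4D array (x, y, z, t).
#' @param wm_mask,csf_mask,brain_mask Logical vectors over voxels (rows of
#'   `data`), or 3D logical arrays when `data` is 4D.
#' @param motion Matrix with 6 columns of head-motion parameter series, or
#'   `NULL` when no motion estimates exist (e.g. simulated data).
#' @param with_global Include the global (brain-mean) signal. Default
#'   `FALSE`.
#' @param n_pcs Number of principal-component series per tissue. Default 5.
#' @return Data frame of named confound columns.
#' @export
extract_nuisance <- function(data, wm_mask, csf_mask, brain_mask,
                             motion = NULL, with_global = FALSE,
                             n_pcs = 5L) {
  if (is.array(data) && length(dim(data)) == 4L) {
    d <- dim(data)
    data <- matrix(data, prod(d[1:3]), d[4L])
    wm_mask <- as.logical(wm_mask)
    csf_mask <- as.logical(csf_mask)
    brain_mask <- as.logical(brain_mask)
  }
  stopifnot(is.matrix(data))
  nt <- ncol(data)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nt || ncol(motion) != 6L)
      stop("`motion` must be a time-by-6 matrix matching the data length")
  }
  if (!any(wm_mask) || !any(csf_mask) || !any(brain_mask))
    stop("masks must be nonempty")

  tissue_pcs <- function(mask, label) {
    vox <- data[mask, , drop = FALSE]
    if (nrow(vox) < n_pcs + 1L)
      stop(sprintf("too few %s voxels (%d) for %d principal components",
                   label, nrow(vox), n_pcs))
    dem <- sweep(vox, 1L, rowMeans(vox))
    pc <- prcomp(t(dem), center = FALSE)
    keep <- seq_len(min(n_pcs, ncol(pc$x)))
    scores <- pc$x[, keep, drop = FALSE]
    sds <- apply(scores, 2L, stats::sd)
    ok <- sds > 1e-10 * max(sds, 1e-300)
    if (!all(ok)) {
      warning(sprintf("%s PCA: dropping %d near-zero-variance components",
                      label, sum(!ok)))
      scores <- scores[, ok, drop = FALSE]
    }
    colnames(scores) <- paste0(label, "_pc", seq_len(ncol(scores)))
    scores
  }

  if (!is.null(motion)) {
    out <- data.frame(motion)
    names(out) <- paste0("motion", 1:6)
  } else {
    out <- data.frame(row.names = seq_len(nt))
  }
  out$wm_mean <- colMeans(data[wm_mask, , drop = FALSE])
  out$csf_mean <- colMeans(data[csf_mask, , drop = FALSE])
  out <- cbind(out, tissue_pcs(wm_mask, "wm"), tissue_pcs(csf_mask, "csf"))
  if (isTRUE(with_global))
    out$global <- colMeans(data[brain_mask, , drop = FALSE])
  out
}

#' Z-normalize a series (population convention)
#'
#' Centers to mean zero and scales to standard deviation one, using the
#' population (1/N) standard deviation. All metrics in the package use this
#' convention, so the zero-lag correlation of two z-scored series is
#' exactly their inner product divided by N.
#'
#' @param x Numeric, nonconstant time series.
#' @return Z-scored series.
#' @export
zscore <- function(x) {
  check_series(x)
  s <- sd_pop(x)
  if (s == 0) stop("degenerate input: constant series cannot be z-scored")
  (x - mean(x)) / s
}

#' Run the full conditioning chain on one series
#'
#' Nuisance regression (if confounds are given) strictly precedes band-pass
#' filtering, then the result is z-scored. The order is fixed: residual
#' time courses are band-pass filtered, never the reverse.
#'
#' @inheritParams butter_lowpass
#' @param confounds Optional confound matrix for [nuisance_regress()].
#' @return Prepared series (z-scored).
#' @export
prepare_series <- function(x, tr, confounds = NULL, spec = filter_spec()) {
  if (!is.null(confounds)) x <- nuisance_regress(x, confounds)
  zscore(bandpass(x, tr, spec))
}
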