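# Group statistics for repeated-run connectivity maps: fixed-effect
# one-sample t maps with BH/FDR thresholding, paired-|T| stability
# matrices across runs and preprocessing pipelines, and the global-signal-
# regression sensitivity ("dubious voxel") report.

#' Benjamini-Hochberg FDR mask
#'
#' Step-up FDR control at level `q`; returns the rejection mask. Backed by
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return Logical vector: `TRUE` where the hypothesis is rejected.
#' @export
fdr_mask <- function(pvals, q) {
  stopifnot(is.numeric(pvals), all(pvals >= 0 & pvals <= 1, na.rm = TRUE),
            q > 0, q < 1)
  p.adjust(pvals, method = "BH") <= q
}

#' Fixed-effect one-sample t map
#'
#' Per voxel, across n run-level maps: `t = mean / (sd / sqrt(n))` with
#' `df = n - 1` (sample sd), two-sided p-values, and a significance mask
#' from Benjamini-Hochberg FDR at level `fdr_q`. Zero-variance voxels get
#' `t = +/-Inf` with `p = 0` and are flagged. A simple unweighted t across
#' the runs of one subject is the fixed-effect analysis appropriate to the
#' single-subject repeated-measures design.
#'
#' @param maps Voxel-by-n numeric matrix (one column per run-level map),
#'   or a list of `conn_map` objects sharing a mask and metric.
#' @param fdr_q FDR level for the significance mask. Default 0.05.
#' @return An object of class `stat_map`: list with `t`, `df`, `p`, `sig`
#'   (FDR mask), `mean`, `fdr_q`, `zero_variance` (flag vector), and
#'   voxel bookkeeping when built from `conn_map`s.
#' @export
one_sample_tmap <- function(maps, fdr_q = 0.05) {
  vox <- NULL
  index <- NULL
  dm <- NULL
  if (is.list(maps) && !is.matrix(maps)) {
    stopifnot(all(vapply(maps, inherits, logical(1L), "conn_map")))
    metrics <- unique(vapply(maps, `[[`, character(1L), "metric"))
    if (length(metrics) != 1L) stop("maps mix metrics")
    idxs <- lapply(maps, `[[`, "index")
    if (!all(vapply(idxs, identical, logical(1L), idxs[[1L]])))
      stop("maps do not share a mask")
    vox <- maps[[1L]]$voxels
    index <- maps[[1L]]$index
    dm <- maps[[1L]]$dim
    maps <- do.call(cbind, lapply(maps, `[[`, "values"))
  }
  stopifnot(is.matrix(maps), ncol(maps) >= 2L)
  n <- ncol(maps)
  mu <- rowMeans(maps)
  s <- apply(maps, 1L, stats::sd)
  zero_var <- s == 0
  tt <- ifelse(zero_var, ifelse(mu == 0, 0, sign(mu) * Inf),
               mu / (s / sqrt(n)))
  p <- ifelse(zero_var, ifelse(mu == 0, 1, 0),
              2 * pt(abs(tt), df = n - 1, lower.tail = FALSE))
  structure(list(t = tt, df = n - 1L, p = p, sig = fdr_mask(p, fdr_q),
                 mean = mu, fdr_q = fdr_q, zero_variance = zero_var,
                 voxels = vox, index = index, dim = dm),
            class = "stat_map")
}

#' Paired |T| between two map sets
#'
#' Two-sided paired t statistic (absolute value) over the included voxels
#' of two run-level (or averaged) maps. With significance masks supplied,
#' the inclusion set is the union policy: voxels significant in at least
#' one of the two maps, with non-significant values retained inside that
#' union (alternatives: `"intersection"`, `"all"`). Identical maps give 0.
#'
#' @param a,b Numeric map vectors of equal length.
#' @param sig_a,sig_b Optional logical significance masks for the two maps.
#' @param policy Inclusion policy when masks are given: `"union"`
#'   (default), `"intersection"` or `"all"`.
#' @return Absolute paired t value (scalar).
#' @export
paired_t_compare <- function(a, b, sig_a = NULL, sig_b = NULL,
                             policy = c("union", "intersection", "all")) {
  policy <- match.arg(policy)
  stopifnot(length(a) == length(b))
  keep <- rep(TRUE, length(a))
  if (!is.null(sig_a) && !is.null(sig_b)) {
    keep <- switch(policy,
                   union = sig_a | sig_b,
                   intersection = sig_a & sig_b,
                   all = keep)
  }
  d <- a[keep] - b[keep]
  if (length(d) < 3L) stop("insufficient data: fewer than 3 shared voxels")
  s <- stats::sd(d)
  if (s == 0) return(if (mean(d) == 0) 0 else Inf)
  abs(mean(d) / (s / sqrt(length(d))))
}

#' Stability matrix of paired |T| values across datasets
#'
#' All pairwise [paired_t_compare()] values over an ordered list of
#' datasets' maps (the conventional ordering is session-major:
#' run1+GSReg, run2+GSReg, run1-GSReg, run2-GSReg, next session, ...).
#' Low |T| between two datasets means the connectivity pattern replicated.
#'
#' @param maps List of numeric map vectors (one per dataset), all equal
#'   length.
#' @param sigs Optional list of logical significance masks (same length).
#' @param labels Dataset labels. Defaults to list names or indices.
#' @param policy Passed to [paired_t_compare()].
#' @return An object of class `stability_matrix`: list with `T_abs`
#'   (symmetric matrix, zero diagonal), `labels`, `mean_offdiag`,
#'   `sd_offdiag`.
#' @export
stability_matrix <- function(maps, sigs = NULL, labels = NULL,
                             policy = "union") {
  k <- length(maps)
  stopifnot(k >= 2L)
  if (is.null(labels)) labels <- names(maps)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      tij <- paired_t_compare(maps[[i]], maps[[j]],
                              if (is.null(sigs)) NULL else sigs[[i]],
                              if (is.null(sigs)) NULL else sigs[[j]],
                              policy = policy)
      m[i, j] <- tij
      m[j, i] <- tij
    }
  }
  off <- m[upper.tri(m)]
  structure(list(T_abs = m, labels = labels,
                 mean_offdiag = mean(off), sd_offdiag = stats::sd(off)),
            class = "stability_matrix")
}

#' Pipeline-unstable ("dubious") voxels under global signal regression
#'
#' Compares per-seed t maps computed with and without global signal
#' regression (GSReg). For correlation and cross-correlation, a dubious
#' voxel is one significantly *negative* with GSReg but no longer
#' significant without it (the classic spurious-anticorrelation pattern).
#' For DTW (a sign-free similarity), a dubious voxel is one that passes
#' the significance threshold under exactly one of the two pipelines
#' (XOR). Counts are reported per seed together with the percentage of the
#' analysis mask.
#'
#' @param tmaps_gsr,tmaps_nogsr Lists of `stat_map` objects (one per
#'   seed), matched element-wise, computed with / without GSReg.
#' @param metric `"correlation"`, `"xcorr"` or `"dtw"` (selects the rule).
#' @param fdr_q FDR level at which the `stat_map`s' masks are re-derived.
#'   Default 0.05.
#' @return An object of class `dubious_report`: list with `counts` (per
#'   seed), `pct` (of mask voxels), `masks` (list of logical vectors),
#'   `n_mask`, `metric`.
#' @export
dubious_voxels <- function(tmaps_gsr, tmaps_nogsr,
                           metric = c("correlation", "xcorr", "dtw"),
                           fdr_q = 0.05) {
  metric <- match.arg(metric)
  stopifnot(length(tmaps_gsr) == length(tmaps_nogsr),
            length(tmaps_gsr) >= 1L)
  seeds <- names(tmaps_gsr)
  if (is.null(seeds)) seeds <- as.character(seq_along(tmaps_gsr))
  masks <- vector("list", length(seeds))
  names(masks) <- seeds
  n_mask <- length(tmaps_gsr[[1L]]$t)
  for (s in seq_along(seeds)) {
    tg <- tmaps_gsr[[s]]
    tn <- tmaps_nogsr[[s]]
    stopifnot(length(tg$t) == n_mask, length(tn$t) == n_mask)
    sig_g <- fdr_mask(tg$p, fdr_q)
    sig_n <- fdr_mask(tn$p, fdr_q)
    masks[[s]] <- if (metric == "dtw") {
      xor(sig_g, sig_n)
    } else {
      sig_g & (tg$t < 0) & !sig_n
    }
  }
  counts <- vapply(masks, sum, integer(1L))
  structure(list(counts = counts, pct = 100 * counts / n_mask,
                 masks = masks, n_mask = n_mask, metric = metric,
                 fdr_q = fdr_q),
            class = "dubious_report")
}

#' @export
print.dubious_report <- function(x, ...) {
  cat(sprintf("dubious voxels (%s, FDR q = %g): total %d of %d voxels (%.2f%%)\n",
              x$metric, x$fdr_q, sum(x$counts), x$n_mask * length(x$counts),
              mean(x$pct)))
  invisible(x)
}
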