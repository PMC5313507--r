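# Simulation experiments: band-limited surrogate signals, empirical null
# distributions, transient-interaction significance grids (time delay x
# shared-segment length), and common-noise robustness sweeps for
# anticorrelated pairs.

#' Generate a band-limited surrogate signal
#'
#' White Gaussian noise passed through the band-pass chain of
#' [bandpass()] (DCT high-pass + bidirectional Butterworth low-pass,
#' 0.009-0.08 Hz with the defaults) and then z-scored. Deterministic for a
#' given seed.
#'
#' @param n_samples Number of samples (>= 50).
#' @param tr Sampling interval, seconds.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param spec A [filter_spec()].
#' @return Numeric series of length `n_samples`, mean 0, population sd 1.
#' @export
gen_surrogate <- function(n_samples, tr = 2, seed = NULL,
                          spec = filter_spec()) {
  stopifnot(n_samples >= 50L)
  check_tr(tr)
  with_seed(seed, zscore(bandpass(rnorm(n_samples), tr, spec)))
}

#' Empirical null distribution of a metric over independent pairs
#'
#' Evaluates the metric on `n_pairs` pairs of independently generated
#' surrogate signals. Significance thresholds follow the direction of each
#' metric: for correlation and cross-correlation the 5th and 95th
#' percentiles of the null values; for DTW the 5th percentile of the
#' distances (strong connection means a distance close to zero).
#'
#' @param metric `"correlation"`, `"xcorr"` or `"dtw"`.
#' @param n_pairs Number of independent surrogate pairs (>= 100).
#' @param n_samples,tr Surrogate geometry, see [gen_surrogate()].
#' @param window_s DTW warping window / maximal cross-correlation lag,
#'   seconds.
#' @param seed Integer seed driving all pair draws.
#' @param spec A [filter_spec()].
#' @return An object of class `null_dist`: list with `metric`, `values`,
#'   `thresholds` (named `q05`/`q95` or `q05`), and the generation
#'   parameters.
#' @export
build_null <- function(metric = c("correlation", "xcorr", "dtw"),
                       n_pairs, n_samples, tr = 2, window_s = 100,
                       seed = NULL, spec = filter_spec()) {
  metric <- match.arg(metric)
  stopifnot(n_pairs >= 100L)
  values <- vapply(seq_len(n_pairs), function(i) {
    x1 <- gen_surrogate(n_samples, tr, child_seed(seed, 2L * i - 1L), spec)
    x2 <- gen_surrogate(n_samples, tr, child_seed(seed, 2L * i), spec)
    eval_metric(x1, x2, metric, tr, window_s)$value
  }, numeric(1L))
  thresholds <- if (metric == "dtw") {
    c(q05 = unname(quantile(values, 0.05)))
  } else {
    c(q05 = unname(quantile(values, 0.05)),
      q95 = unname(quantile(values, 0.95)))
  }
  structure(list(metric = metric, values = values, thresholds = thresholds,
                 n_pairs = n_pairs, n_samples = n_samples, tr = tr,
                 window_s = window_s, seed = seed),
            class = "null_dist")
}

# Significance of a metric value against its null thresholds.
null_significant <- function(value, null) {
  th <- null$thresholds
  if (null$metric == "dtw") value < th[["q05"]]
  else value < th[["q05"]] || value > th[["q95"]]
}

#' Pair of signals with a transient shared segment
#'
#' Models a transient interaction by copying the first `shared_s` seconds
#' of one surrogate into an independently generated surrogate at offset
#' `delay_s` (overwriting, not adding), then re-z-scoring both. At zero
#' delay the expected zero-lag correlation is approximately the shared
#' fraction `shared_s / total_s`.
#'
#' @param total_s Total duration, seconds.
#' @param shared_s Duration of the shared segment, seconds.
#' @param delay_s Offset of the shared segment in the second signal,
#'   seconds. Requires `shared_s + delay_s <= total_s`.
#' @param tr Sampling interval, seconds.
#' @param seed Optional integer seed.
#' @param spec A [filter_spec()].
#' @return List with series `x1`, `x2`.
#' @export
transient_pair <- function(total_s, shared_s, delay_s, tr = 2, seed = NULL,
                           spec = filter_spec()) {
  check_tr(tr)
  if (shared_s + delay_s > total_s)
    stop("infeasible geometry: shared_s + delay_s must not exceed total_s")
  n <- window_to_samples(total_s, tr)
  ls <- window_to_samples(shared_s, tr)
  dn <- window_to_samples(delay_s, tr)
  if (ls < 1L) stop("shared segment must contain at least one sample")
  with_seed(seed, {
    x1 <- gen_surrogate(n, tr, NULL, spec)
    x2 <- gen_surrogate(n, tr, NULL, spec)
    x2[(dn + 1L):(dn + ls)] <- x1[seq_len(ls)]
    list(x1 = zscore(x1), x2 = zscore(x2))
  })
}

#' Transient-interaction significance grid
#'
#' Replicates the transient-interaction simulation: over a grid of time
#' delays and shared-segment lengths, `n_reps` independent transient pairs
#' are generated per cell and each metric's median value is flagged
#' significant when it crosses that metric's empirical null threshold.
#' Correlation captures the interaction only near zero delay; DTW with a
#' short window behaves like correlation, while DTW with a long window
#' detects the shared segment at any delay within the window, provided the
#' segment is long enough.
#'
#' @param delays_s Grid of time delays, seconds.
#' @param lengths_s Grid of shared-segment lengths, seconds.
#' @param total_s Total signal duration, seconds. Default 600.
#' @param tr Sampling interval, seconds. Default 2.
#' @param dtw_windows_s DTW warping windows to evaluate, seconds.
#' @param n_reps Pairs per cell. Default 10.
#' @param nulls Optional named list of `null_dist` objects (names
#'   `"correlation"` and `"dtw_w<window>"`); built on demand when `NULL`.
#' @param null_pairs Pairs for on-demand nulls. Default 1000.
#' @param seed Integer seed.
#' @param spec A [filter_spec()].
#' @return An object of class `interaction_grid`: data frame with columns
#'   `delay_s`, `length_s`, `metric`, `value` (median over reps) and
#'   `significant`, plus the nulls as an attribute.
#' @export
run_interaction_grid <- function(delays_s = seq(0, 100, by = 4),
                                 lengths_s = seq(60, 600, by = 60),
                                 total_s = 600, tr = 2,
                                 dtw_windows_s = c(4, 100),
                                 n_reps = 10L, nulls = NULL,
                                 null_pairs = 1000L, seed = NULL,
                                 spec = filter_spec()) {
  check_tr(tr)
  n <- window_to_samples(total_s, tr)
  metric_names <- c("correlation", paste0("dtw_w", dtw_windows_s))
  if (is.null(nulls)) {
    nulls <- list(correlation = build_null("correlation", null_pairs, n, tr,
                                           seed = child_seed(seed, 1L),
                                           spec = spec))
    for (iw in seq_along(dtw_windows_s)) {
      wlab <- paste0("dtw_w", dtw_windows_s[iw])
      nulls[[wlab]] <- build_null("dtw", null_pairs, n, tr,
                                  window_s = dtw_windows_s[iw],
                                  seed = child_seed(seed, 1L + iw),
                                  spec = spec)
    }
  }
  if (!all(metric_names %in% names(nulls)))
    stop("`nulls` must provide entries: ", paste(metric_names, collapse = ", "))
  ws <- vapply(dtw_windows_s, window_to_samples, integer(1L), tr = tr)

  grid <- expand.grid(delay_s = delays_s, length_s = lengths_s,
                      KEEP.OUT.ATTRS = FALSE)
  cell_id <- 0L
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    delay <- grid$delay_s[g]
    len <- grid$length_s[g]
    feasible <- delay + len <= total_s
    vals <- matrix(NA_real_, n_reps, length(metric_names),
                   dimnames = list(NULL, metric_names))
    if (feasible) {
      for (r in seq_len(n_reps)) {
        cell_id <- cell_id + 1L
        pr <- transient_pair(total_s, len, delay, tr,
                             child_seed(seed, 100L + cell_id), spec)
        vals[r, "correlation"] <- cor(pr$x1, pr$x2)
        for (iw in seq_along(ws))
          vals[r, 1L + iw] <- dtw_distance(pr$x1, pr$x2, ws[iw])
      }
    }
    med <- apply(vals, 2L, median)
    sig <- vapply(metric_names, function(mn) {
      if (!feasible) return(NA)
      null_significant(med[[mn]], nulls[[mn]])
    }, logical(1L))
    rows[[g]] <- data.frame(delay_s = delay, length_s = len,
                            metric = metric_names, value = unname(med),
                            significant = unname(sig),
                            row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "nulls") <- nulls
  attr(out, "params") <- list(total_s = total_s, tr = tr, n_reps = n_reps,
                              dtw_windows_s = dtw_windows_s, seed = seed)
  class(out) <- c("interaction_grid", "data.frame")
  out
}

#' Calibrate the noise amplitude of an anticorrelated sinusoid pair
#'
#' Finds, by bisection, the amplitude of independent band-passed noise
#' that—added to two opposite-phase sinusoids—brings the expected Pearson
#' correlation of the pair to `target_r`. The expectation is estimated over
#' a fixed batch of noise draws (so the objective is continuous and
#' monotone in the amplitude), to a tolerance of 0.005.
#'
#' @inheritParams anticorr_pair
#' @param calib_pairs Size of the calibration batch. Default 50.
#' @return The calibrated noise amplitude (scalar).
#' @export
calibrate_anticorr_noise <- function(freq_hz = 0.08, target_r = -0.86,
                                     n_samples = 300L, tr = 2, seed = NULL,
                                     calib_pairs = 50L,
                                     spec = filter_spec()) {
  if (!(target_r > -1 && target_r < 0))
    stop("`target_r` must lie in (-1, 0)")
  t <- (seq_len(n_samples) - 1L) * tr
  s1 <- zscore(sin(2 * pi * freq_hz * t))
  s2 <- -s1
  noise <- lapply(seq_len(calib_pairs), function(i) {
    list(n1 = gen_surrogate(n_samples, tr, child_seed(seed, 5000L + 2L * i),
                            spec),
         n2 = gen_surrogate(n_samples, tr, child_seed(seed, 5001L + 2L * i),
                            spec))
  })
  mean_r <- function(a) {
    mean(vapply(noise, function(nz)
      cor(s1 + a * nz$n1, s2 + a * nz$n2), numeric(1L)))
  }
  lo <- 0
  hi <- 1
  while (mean_r(hi) < target_r) {
    hi <- hi * 2
    if (hi > 64) stop("calibration failure: target correlation unreachable")
  }
  for (it in seq_len(60L)) {
    mid <- (lo + hi) / 2
    r <- mean_r(mid)
    if (abs(r - target_r) < 0.005) return(mid)
    if (r < target_r) lo <- mid else hi <- mid
  }
  stop("calibration failure: bisection did not converge")
}

#' Anticorrelated sinusoid pair with calibrated independent noise
#'
#' Two opposite-phase sinusoids at `freq_hz` plus independent band-passed
#' Gaussian noise whose amplitude is calibrated (see
#' [calibrate_anticorr_noise()]) so that the expected correlation of the
#' pair is `target_r`. With zero noise the correlation is exactly -1.
#'
#' @param freq_hz Sinusoid frequency, Hz. Default 0.08.
#' @param target_r Target Pearson correlation in (-1, 0). Default -0.86.
#' @param n_samples Number of samples. Default 300.
#' @param tr Sampling interval, seconds. Default 2.
#' @param seed Optional integer seed.
#' @param noise_amp Optional precomputed noise amplitude (skips
#'   calibration; use 0 for the pure anti-phase pair).
#' @param spec A [filter_spec()].
#' @return List with `x1`, `x2` (z-scored), `noise_amp` and `realized_r`.
#' @export
anticorr_pair <- function(freq_hz = 0.08, target_r = -0.86,
                          n_samples = 300L, tr = 2, seed = NULL,
                          noise_amp = NULL, spec = filter_spec()) {
  check_tr(tr)
  if (is.null(noise_amp))
    noise_amp <- calibrate_anticorr_noise(freq_hz, target_r, n_samples, tr,
                                          seed, spec = spec)
  t <- (seq_len(n_samples) - 1L) * tr
  s1 <- zscore(sin(2 * pi * freq_hz * t))
  s2 <- -s1
  n1 <- gen_surrogate(n_samples, tr, child_seed(seed, 1L), spec)
  n2 <- gen_surrogate(n_samples, tr, child_seed(seed, 2L), spec)
  x1 <- zscore(s1 + noise_amp * n1)
  x2 <- zscore(s2 + noise_amp * n2)
  list(x1 = x1, x2 = x2, noise_amp = noise_amp, realized_r = cor(x1, x2))
}

#' Common-noise robustness sweep
#'
#' Mixes a single band-passed common-noise signal into both members of a
#' pair with weight `alpha`: `mixed_i = zscore((1 - alpha) * x_i +
#' alpha * common)`, and records correlation and DTW distance per weight,
#' with significance flags against the supplied nulls. The common signal
#' emulates a global (e.g. physiological) component: it biases the
#' correlation toward zero/positive values while the DTW distance of a
#' genuinely coupled pair stays below its null threshold.
#'
#' @param pair List with `x1`, `x2` (e.g. from [anticorr_pair()]).
#' @param alphas Common-noise weights in `[0, 0.5]`.
#' @param null_r,null_dtw `null_dist` objects for correlation and DTW
#'   (the DTW null must be built at the same `window_s`).
#' @param window_s DTW warping window, seconds. Default 8: following the
#'   rule that the window should cover the longest expected time lag, the
#'   anti-phase lag of a 0.08 Hz signal is its half-period, 6.25 s, and
#'   8 s is the smallest even multiple of the 2 s sampling interval above
#'   it. (A much larger window lets the warping shrink the *null* pairs'
#'   distances and erodes the contrast.)
#' @param tr Sampling interval, seconds. Default 2.
#' @param seed Optional integer seed (drives the common-noise draw).
#' @param spec A [filter_spec()].
#' @return An object of class `noise_sweep`: data frame with columns
#'   `alpha`, `r`, `r_significant`, `dtw`, `dtw_significant`.
#' @export
common_noise_sweep <- function(pair, alphas = seq(0, 0.5, by = 0.05),
                               null_r, null_dtw, window_s = 8, tr = 2,
                               seed = NULL, spec = filter_spec()) {
  stopifnot(all(alphas >= 0), all(alphas <= 0.5))
  alphas <- sort(alphas)
  n <- length(pair$x1)
  common <- gen_surrogate(n, tr, child_seed(seed, 99L), spec)
  w <- window_to_samples(window_s, tr)
  rows <- lapply(alphas, function(a) {
    m1 <- zscore((1 - a) * pair$x1 + a * common)
    m2 <- zscore((1 - a) * pair$x2 + a * common)
    r <- cor(m1, m2)
    d <- dtw_distance(m1, m2, w)
    data.frame(alpha = a, r = r,
               r_significant = null_significant(r, null_r),
               dtw = d, dtw_significant = null_significant(d, null_dtw))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("noise_sweep", "data.frame")
  out
}
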