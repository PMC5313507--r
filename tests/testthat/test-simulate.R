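# Surrogates, nulls, transient pairs, anticorrelated pairs, noise sweeps,
# and the synthetic fMRI fixture generator.

test_that("surrogates are seed-deterministic, unit-variance, band-limited", {
  a <- gen_surrogate(300, 2, seed = 1)
  b <- gen_surrogate(300, 2, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, gen_surrogate(300, 2, seed = 2)))
  expect_equal(mean(a), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(a^2)), 1, tolerance = 1e-12)
  # spectral mass concentrated in the 0.009-0.08 Hz band (periodogram)
  frac_out <- vapply(1:50, function(i) {
    x <- gen_surrogate(300, 2, seed = i)
    sp <- stats::spec.pgram(stats::ts(x, deltat = 2), plot = FALSE,
                            taper = 0, detrend = FALSE)
    sum(sp$spec[sp$freq < 0.009 * 0.8 | sp$freq > 0.08 * 1.2]) /
      sum(sp$spec)
  }, numeric(1))
  expect_lt(mean(frac_out), 0.15)
})

test_that("null distributions are centred (r) and directional (dtw)", {
  nr <- build_null("correlation", 1000, 300, 2, seed = 11)
  expect_length(nr$values, 1000)
  expect_lt(abs(mean(nr$values)), 0.02)
  expect_lt(abs(nr$thresholds[["q05"]] + nr$thresholds[["q95"]]), 0.03)
  expect_equal(nr$thresholds[["q05"]],
               unname(quantile(nr$values, 0.05)))
  nd <- build_null("dtw", 200, 300, 2, window_s = 100, seed = 12)
  expect_named(nd$thresholds, "q05")
  expect_true(all(nd$values > 0))
  s <- to_similarity(nd$values, unit = "matrix")$similarities
  expect_equal(mean(s), 0, tolerance = 1e-10)
})

test_that("null thresholds are stable in the pair count", {
  n1 <- build_null("dtw", 400, 150, 2, window_s = 100, seed = 21)
  n2 <- build_null("dtw", 1600, 150, 2, window_s = 100, seed = 22)
  rel <- abs(n1$thresholds[["q05"]] - n2$thresholds[["q05"]]) /
    n2$thresholds[["q05"]]
  expect_lt(rel, 0.05)
})

test_that("transient pairs carry the planted shared fraction", {
  # full overlap at zero delay: identical signals
  p <- transient_pair(600, 600, 0, 2, seed = 1)
  expect_equal(cor(p$x1, p$x2), 1)
  # half overlap: r ~ L / T = 0.5
  rs <- vapply(1:200, function(i)
    with(transient_pair(600, 300, 0, 2, seed = i), cor(x1, x2)),
    numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.07)
  # delayed short segment: zero-lag r not significant in most draws
  nr <- build_null("correlation", 200, 300, 2, seed = 31)
  sig <- vapply(1:100, function(i) {
    p <- transient_pair(600, 120, 60, 2, seed = 400 + i)
    r <- cor(p$x1, p$x2)
    r < nr$thresholds[["q05"]] || r > nr$thresholds[["q95"]]
  }, logical(1))
  expect_lt(mean(sig), 0.10)
  expect_error(transient_pair(600, 500, 200, 2), "infeasible")
})

test_that("anticorrelated pair calibration reaches the target", {
  p0 <- anticorr_pair(seed = 1, noise_amp = 0)
  expect_equal(p0$realized_r, -1)
  amp <- calibrate_anticorr_noise(seed = 42)
  rr <- vapply(1:100, function(i)
    anticorr_pair(seed = 500 + i, noise_amp = amp)$realized_r, numeric(1))
  expect_gt(mean(rr), -0.89)
  expect_lt(mean(rr), -0.83)
  # realized |r| decreases as the noise amplitude grows
  amps <- c(0, 0.2, 0.4, 0.8, 1.6)
  mean_r <- vapply(amps, function(a)
    mean(vapply(1:40, function(i)
      anticorr_pair(seed = 700 + i, noise_amp = a)$realized_r,
      numeric(1))), numeric(1))
  expect_true(all(diff(abs(mean_r)) < 0))
})

test_that("common-noise sweep: alpha 0 is the clean pair; r rises to 0", {
  nr <- build_null("correlation", 200, 300, 2, seed = 61)
  nd <- build_null("dtw", 200, 300, 2, window_s = 8, seed = 62)
  p <- anticorr_pair(seed = 9, noise_amp = 0.4)
  sw <- common_noise_sweep(p, null_r = nr, null_dtw = nd, seed = 9)
  expect_equal(sw$alpha, seq(0, 0.5, by = 0.05))
  expect_equal(sw$r[1], p$realized_r)
  expect_equal(sw$dtw[1],
               dtw_distance(p$x1, p$x2, window_to_samples(8, 2)))
  # correlation drifts monotonically toward zero with the common noise
  expect_gt(cor(sw$alpha, sw$r), 0.95)
  expect_true(sw$r_significant[1])
})

test_that("interaction grid reproduces the three metric signatures", {
  # scaled-down grid: the full acceptance-scale grid lives in the
  # acceptance suite
  nulls <- list(
    correlation = build_null("correlation", 200, 300, 2, seed = 101),
    dtw_w4 = build_null("dtw", 200, 300, 2, window_s = 4, seed = 102),
    dtw_w100 = build_null("dtw", 200, 300, 2, window_s = 100, seed = 103))
  g <- run_interaction_grid(delays_s = c(0, 60), lengths_s = c(120, 540),
                            n_reps = 5, nulls = nulls, seed = 7)
  expect_s3_class(g, "interaction_grid")
  expect_equal(nrow(g), 2 * 2 * 3)
  gd <- as.data.frame(g)
  at <- function(m, delay, len)
    gd$significant[gd$metric == m & gd$delay_s == delay & gd$length_s == len]
  # zero delay, long segment: everything fires
  expect_true(at("correlation", 0, 540))
  expect_true(at("dtw_w4", 0, 540))
  expect_true(at("dtw_w100", 0, 540))
  # long delay, long segment: only the wide DTW window
  expect_false(at("correlation", 60, 540))
  expect_false(at("dtw_w4", 60, 540))
  expect_true(at("dtw_w100", 60, 540))
})

test_that("synthetic fixtures honour their ground truth", {
  fx <- synth_fmri(seed = 3)
  expect_identical(fx$bold, synth_fmri(seed = 3)$bold)  # byte-identical
  d <- dim(fx$bold)
  expect_equal(d[1:3], fx$config$dim_xyz)
  expect_equal(sum(fx$masks$gm), sum(fx$truth$tissue == "gm"))
  expect_equal(as.integer(fx$atlas[fx$truth$voxel[fx$truth$network == 2]]),
               rep(2L, sum(fx$truth$network == 2)))
  # noiseless single network: member voxels perfectly coherent
  fx0 <- synth_fmri(n_networks = 1, lags_s = 0, noise_sd = 0,
                    voxels_per_network = 5, n_gm_null = 5, seed = 4)
  vox <- matrix(fx0$bold, prod(dim(fx0$bold)[1:3]))[
    fx0$truth$voxel[fx0$truth$network == 1], ]
  cc <- cor(t(vox))
  expect_equal(max(abs(cc - 1)), 0, tolerance = 1e-12)
  # a planted global signal inflates pairwise correlations
  mean_r <- function(gw, seed) {
    f <- synth_fmri(global_weight = gw, seed = seed)
    gm <- matrix(f$bold, prod(dim(f$bold)[1:3]))[f$truth$tissue == "gm", ]
    cc <- cor(t(gm))
    mean(cc[upper.tri(cc)])
  }
  rs <- vapply(1:5, function(i)
    mean_r(0.4, 800 + i) - mean_r(0, 800 + i), numeric(1))
  expect_gt(mean(rs), 0.02)
})

test_that("a delayed network is seen by wide-window DTW but not by r", {
  # the cross-network DTW similarity (null mean minus distance) should be
  # positive — the 30 s shift is inside the 100 s window so the pair is
  # far more alike than independent signals — while the zero-lag r stays
  # near zero; aligning a shifted pair keeps O(shift) boundary costs at
  # the matrix corners, so the claim is about the similarity's sign and
  # mean, not about every seed beating the null's 5th percentile
  null_d <- build_null("dtw", 200, 300, 2, window_s = 100, seed = 950)
  sims <- numeric(10)
  rs <- numeric(10)
  for (i in 1:10) {
    fx <- synth_fmri(n_networks = 2, lags_s = c(0, 30), noise_sd = 0.3,
                     voxels_per_network = 6, n_gm_null = 10,
                     n_volumes = 300, seed = 900 + i)
    flat <- matrix(fx$bold, prod(dim(fx$bold)[1:3]))
    v1 <- zscore(bandpass(flat[fx$truth$voxel[fx$truth$network == 1][1], ], 2))
    v2 <- zscore(bandpass(flat[fx$truth$voxel[fx$truth$network == 2][1], ], 2))
    sims[i] <- mean(null_d$values) - dtw_distance(v1, v2, 50)
    rs[i] <- cor(v1, v2)
  }
  expect_gte(sum(sims > 0), 9)
  expect_lt(stats::t.test(sims, alternative = "greater")$p.value, 0.01)
  expect_gte(sum(abs(rs) < 0.3), 8)
})

test_that("fixtures round-trip through NIfTI/TSV/JSON", {
  fx <- synth_fmri(dim_xyz = c(6, 6, 3), n_volumes = 60, seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_synth_fmri(fx, dir)
  expect_true(all(file.exists(paths)))
  back <- dtwfc:::read_fixture(dir)
  expect_equal(as.vector(back$bold), as.vector(fx$bold), tolerance = 1e-6)
  expect_equal(back$gm, fx$masks$gm, ignore_attr = TRUE)
  expect_equal(back$config$tr, fx$tr)
})
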