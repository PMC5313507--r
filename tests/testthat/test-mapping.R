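# Seed maps, ROI series, connectivity matrices, feature vectors.

prepped_fixture <- function(seed, ...) {
  fx <- synth_fmri(seed = seed, ...)
  list(fx = fx, prep = prep_fixture(fx))
}

test_that("seed maps carry the metric's self-value at the seed", {
  pf <- prepped_fixture(1)
  seed_vox <- pf$fx$truth$voxel[pf$fx$truth$network == 1][1]
  for (m in c("correlation", "xcorr", "dtw")) {
    sm <- seed_map(pf$prep, pf$fx$masks$gm, seed_vox, metric = m,
                   tr = 2, window_s = 100)
    at_seed <- which(sm$index == seed_vox)
    if (m == "dtw") {
      expect_equal(sm$raw[at_seed], 0)                 # distance 0 to itself
      expect_equal(sm$values[at_seed], max(sm$values)) # largest similarity
      expect_equal(mean(sm$values), 0, tolerance = 1e-10)
    } else {
      expect_equal(sm$values[at_seed], 1)
    }
    expect_equal(length(sm$values), sum(pf$fx$masks$gm))
  }
  expect_error(seed_map(pf$prep, pf$fx$masks$gm,
                        pf$fx$truth$voxel[pf$fx$truth$tissue == "wm"][1],
                        metric = "correlation", tr = 2),
               "outside the mask")
})

test_that("maps recover the planted network structure", {
  # same-network voxels correlate strongly; nulls stay low; the delayed
  # network is picked up by the DTW similarity map, not the r map
  aucs <- matrix(NA_real_, 5, 3,
                 dimnames = list(NULL, c("correlation", "xcorr", "dtw")))
  dtw_delayed <- logical(5)
  r_delayed <- logical(5)
  for (i in 1:5) {
    pf <- prepped_fixture(100 + i, noise_sd = 0.4, n_volumes = 300L)
    truth_gm <- pf$fx$truth[pf$fx$truth$tissue == "gm", ]
    seed_vox <- truth_gm$voxel[truth_gm$network == 1][1]
    own <- truth_gm$network == 1 & truth_gm$voxel != seed_vox
    null <- truth_gm$network == 0
    for (m in colnames(aucs)) {
      sm <- seed_map(pf$prep, pf$fx$masks$gm, seed_vox, metric = m,
                     tr = 2, window_s = 100)
      v <- if (m == "dtw") sm$values else abs(sm$values)
      keep <- own[match(sm$index, truth_gm$voxel)]
      nul <- null[match(sm$index, truth_gm$voxel)]
      # AUC of planted vs null voxels
      ranks <- rank(c(v[keep], v[nul]))
      n1 <- sum(keep)
      aucs[i, m] <- (sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2) /
        (n1 * sum(nul))
      if (m == "correlation") {
        r_net1 <- sm$values[keep]
        expect_gt(min(r_net1), 0.5)
      }
    }
    # delayed network (30 s): DTW similarity clearly positive, r near zero
    sm_d <- seed_map(pf$prep, pf$fx$masks$gm, seed_vox, "dtw", tr = 2,
                     window_s = 100)
    sm_r <- seed_map(pf$prep, pf$fx$masks$gm, seed_vox, "correlation",
                     tr = 2)
    lagged <- truth_gm$network == 2
    tt <- stats::t.test(sm_d$values[lagged], sm_d$values[null],
                        alternative = "greater")
    dtw_delayed[i] <- tt$p.value < 0.05
    r_delayed[i] <- abs(mean(sm_r$values[lagged])) < 0.25
  }
  expect_true(all(aucs > 0.95))
  expect_gte(sum(dtw_delayed), 4)
  expect_gte(sum(r_delayed), 4)
})

test_that("ROI series average members and recover sources", {
  fx <- synth_fmri(noise_sd = 0.3, seed = 7)
  ts <- roi_timeseries(fx$bold, fx$atlas)
  expect_equal(colnames(ts), c("1", "2"))
  expect_equal(nrow(ts), fx$config$n_volumes)
  expect_gt(cor(ts[, "1"], fx$sources[1, ]), 0.99)
  # label ordering is ascending regardless of request order
  ts2 <- roi_timeseries(fx$bold, fx$atlas, labels = c(2, 1))
  expect_equal(colnames(ts2), c("1", "2"))
  expect_warning(roi_timeseries(fx$bold, fx$atlas, labels = c(1, 2, 9)),
                 "empty label")
  expect_error(roi_timeseries(fx$bold, fx$atlas[1:2, , ]), "grid")
  # independent sources give uncorrelated ROI series
  fx2 <- synth_fmri(lags_s = c(0, NA), noise_sd = 0.2, seed = 8)
  ts3 <- roi_timeseries(fx2$bold, fx2$atlas)
  expect_lt(abs(cor(ts3[, 1], ts3[, 2])), 0.3)
})

test_that("connectivity matrices are symmetric with metric self-values", {
  set.seed(9)
  series <- sapply(1:6, function(i) gen_surrogate(100, 2, seed = 40 + i))
  colnames(series) <- paste0("roi", 1:6)
  for (m in c("correlation", "xcorr", "dtw")) {
    cm <- connectivity_matrix(series, metric = m, tr = 2, window_s = 60)
    expect_identical(cm$values, t(cm$values))
    expect_equal(unname(diag(cm$values)),
                 rep(if (m == "dtw") 0 else 1, 6))
    expect_equal(dim(cm$values), c(6, 6))
  }
  # identical series everywhere
  same <- series[, rep(1, 4)]
  colnames(same) <- paste0("r", 1:4)
  cm <- connectivity_matrix(same, "correlation", tr = 2)
  expect_equal(unname(cm$values), matrix(1, 4, 4))
  cm <- connectivity_matrix(same, "dtw", tr = 2)
  expect_equal(unname(cm$values), matrix(0, 4, 4))
})

test_that("feature vectors are row-major upper triangles that round-trip", {
  m <- matrix(0, 3, 3)
  m[upper.tri(m)] <- 0  # placeholder
  m <- rbind(c(1, 4, 5), c(4, 1, 6), c(5, 6, 1))
  fv <- matrix_to_features(m)
  expect_equal(unname(fv), c(4, 5, 6))
  expect_equal(names(fv), c("1_2", "1_3", "2_3"))
  expect_equal(features_to_matrix(fv, self = 1), m, ignore_attr = TRUE)
  # n = 90 gives 4005 features
  big <- diag(90)
  big[upper.tri(big)] <- seq_len(4005)
  big <- big + t(big) - diag(diag(big))
  fv90 <- matrix_to_features(big)
  expect_length(fv90, 4005)
  expect_equal(features_to_matrix(fv90), big, ignore_attr = TRUE)
  # random symmetric round-trip
  set.seed(10)
  for (n in c(4, 7, 12)) {
    s <- matrix(rnorm(n * n), n)
    s <- (s + t(s)) / 2
    diag(s) <- 1
    expect_equal(features_to_matrix(matrix_to_features(s)), s,
                 ignore_attr = TRUE)
  }
  expect_error(matrix_to_features(matrix(rnorm(9), 3)), "asymmetric")
  # DTW conn_matrix features pass through the similarity transform
  series <- sapply(1:5, function(i) gen_surrogate(80, 2, seed = 70 + i))
  cm <- connectivity_matrix(series, "dtw", tr = 2, window_s = 40)
  fv <- matrix_to_features(cm)
  expect_length(fv, 10)
  expect_equal(mean(fv), 0, tolerance = 1e-10)
  raw <- dtwfc:::upper_tri_rowmajor(cm$values)
  expect_equal(unname(fv), mean(raw) - raw)
})
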