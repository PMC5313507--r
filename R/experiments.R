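# Higher-level experiment drivers combining the fixture generator, the
# conditioning chain, seed maps and group statistics.

#' Prepare all gray-matter voxels of a synthetic fixture
#'
#' Runs the conditioning chain (nuisance regression with WM/CSF means and
#' principal components, optionally the global signal, then band-pass and
#' z-scoring) on every gray-matter voxel of a [synth_fmri()] fixture.
#'
#' @param fx A `synth_fmri` object.
#' @param gsr Include global signal regression. Default `FALSE`.
#' @param spec A [filter_spec()].
#' @return 4D array of the same geometry with prepared GM voxel series
#'   (other voxels unchanged).
#' @export
prep_fixture <- function(fx, gsr = FALSE, spec = filter_spec()) {
  stopifnot(inherits(fx, "synth_fmri"))
  conf <- extract_nuisance(fx$bold, fx$masks$wm, fx$masks$csf,
                           fx$masks$brain, with_global = gsr)
  d <- dim(fx$bold)
  flat <- matrix(fx$bold, prod(d[1:3]), d[4L])
  for (v in which(fx$masks$gm))
    flat[v, ] <- prepare_series(flat[v, ], fx$tr, conf, spec)
  array(flat, d)
}

#' Global-signal-regression sensitivity experiment on synthetic fixtures
#'
#' Emulates the GSReg sensitivity analysis: several runs of a subject with
#' a planted global signal are generated, each preprocessed twice (with
#' and without GSReg); seed maps for all three metrics are computed per
#' run and pipeline, turned into fixed-effect t maps across runs, and
#' compared with [dubious_voxels()]. The seed is the first voxel of
#' network 1.
#'
#' @param n_runs Runs (repeated measurements) per pipeline. Default 6.
#' @param fdr_q FDR level for the significance masks. Default 0.05.
#' @param window_s DTW window / maximal lag, seconds. Default 100.
#' @param seed Integer seed; run r uses a derived child seed.
#' @param ... Passed to [synth_fmri()]. The default fixture plants a
#'   global signal plus four populations beside a majority of null
#'   gray-matter voxels: the seed's own network; a 30 s delayed copy (the
#'   lagged "anticorrelation" DTW is built to capture); a fully masked
#'   weak negated copy whose zero-lag anticorrelation cancels against the
#'   shared global component and surfaces only after GSReg (zero-lag
#'   correlation's characteristic dubious regime); and a stronger negated
#'   copy whose anticorrelation sits below the maximal-lag search's noise
#'   ceiling without GSReg but clears it with GSReg (the maximal-lag
#'   cross-correlation's dubious regime). The corr-dubious population is
#'   twice the size of the xcorr-dubious one, emulating the relative
#'   extent of the two phenomena in real data.
#' @return List with per-metric `dubious_report`s (`correlation`, `xcorr`,
#'   `dtw`) and the per-metric dubious counts (`counts`).
#' @export
gsr_dubious_experiment <- function(n_runs = 6L, fdr_q = 0.05,
                                   window_s = 100, seed = NULL, ...) {
  args <- modifyList(list(n_networks = 4L,
                          voxels_per_network = c(12L, 12L, 20L, 10L),
                          lags_s = c(0, 30, 0, 0),
                          coupling = c(1, 1, -0.12, -0.35),
                          n_gm_null = 60L, global_weight = 0.35,
                          noise_sd = 0.6),
                     list(...))
  metrics <- c("correlation", "xcorr", "dtw")
  maps <- list()
  fx1 <- NULL
  for (r in seq_len(n_runs)) {
    fx <- do.call(synth_fmri, c(args, list(seed = child_seed(seed, r))))
    if (r == 1L) fx1 <- fx
    seed_vox <- fx$truth$voxel[fx$truth$network == 1L][1L]
    for (gsr in c(TRUE, FALSE)) {
      prep <- prep_fixture(fx, gsr = gsr)
      for (m in metrics) {
        key <- paste(m, if (gsr) "gsr" else "nogsr", sep = "_")
        maps[[key]][[r]] <- seed_map(prep, fx$masks$gm, seed_vox,
                                     metric = m, tr = fx$tr,
                                     window_s = window_s)
      }
    }
  }
  reports <- list()
  for (m in metrics) {
    tg <- one_sample_tmap(maps[[paste0(m, "_gsr")]], fdr_q = fdr_q)
    tn <- one_sample_tmap(maps[[paste0(m, "_nogsr")]], fdr_q = fdr_q)
    reports[[m]] <- dubious_voxels(list(seed1 = tg), list(seed1 = tn),
                                   metric = m, fdr_q = fdr_q)
  }
  list(correlation = reports$correlation, xcorr = reports$xcorr,
       dtw = reports$dtw,
       counts = vapply(reports, function(r) sum(r$counts), integer(1L)),
       fixture = fx1)
}

#' Synthetic connectome classification dataset
#'
#' Instance-by-feature table emulating the structure of the connectome
#' classification experiment: subjects with several runs each, a binary
#' label per subject, standard-normal noise features, and a handful of
#' informative features shifted by `snr` in the label-1 group. The default
#' label split is slightly imbalanced (11 vs 9 of 20 subjects), mirroring
#' the usual situation in real cohorts; under leave-subject-out CV with an
#' exactly balanced split, a fully shrunk model's intercept always lands
#' on the wrong side of 0.5 for the held-out subject, an anti-learning
#' artifact that says nothing about the features.
#'
#' @param n_subjects Number of subjects. Default 20.
#' @param n_runs Runs per subject. Default 5.
#' @param n_features Number of features. Default 300.
#' @param n_informative Number of informative features. Default 5 (set 0
#'   for a null dataset).
#' @param snr Mean shift of informative features in the label-1 group.
#'   Default 2.
#' @param n_positive Subjects with label 1. Default `ceiling(0.55 *
#'   n_subjects)`.
#' @param seed Optional integer seed.
#' @return A [classification_dataset()].
#' @export
synth_classification_dataset <- function(n_subjects = 20L, n_runs = 5L,
                                         n_features = 300L,
                                         n_informative = 5L, snr = 2,
                                         n_positive =
                                           ceiling(0.55 * n_subjects),
                                         seed = NULL) {
  stopifnot(n_positive >= 1L, n_positive < n_subjects,
            n_informative <= n_features)
  with_seed(seed, {
    subject <- rep(sprintf("s%02d", seq_len(n_subjects)), each = n_runs)
    y_subj <- c(rep(1L, n_positive), rep(0L, n_subjects - n_positive))
    y <- rep(y_subj, each = n_runs)
    X <- matrix(rnorm(n_subjects * n_runs * n_features),
                n_subjects * n_runs, n_features)
    if (n_informative > 0L)
      X[, seq_len(n_informative)] <- X[, seq_len(n_informative)] + snr * y
    classification_dataset(X, y, subject)
  })
}
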