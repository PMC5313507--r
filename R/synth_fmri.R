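# Synthetic 4D fMRI fixture generator. Emulates the statistical structure
# the downstream analyses assume: a small voxel grid holding a few
# networks, each driven by a band-limited latent source (optionally a
# delayed copy of a master source, to plant lagged/"anticorrelated"
# couplings), plus voxelwise Gaussian noise and an additive global signal
# shared by all brain voxels. WM and CSF compartments carry their own
# noise so the nuisance-extraction chain has something to work on.

#' Generate a synthetic 4D fMRI dataset with known network structure
#'
#' Voxels are laid out on a small 3D grid. The first
#' `n_networks * voxels_per_network` gray-matter voxels belong to the
#' networks; a WM block, a CSF block and background-brain voxels follow.
#' Network k's source is the master source circularly delayed by
#' `lags_s[k]` seconds, or an independent surrogate when `lags_s[k]` is
#' `NA`. Each member voxel is `source + noise_sd * white noise +
#' global_weight * global`, where the global signal is one extra
#' band-limited surrogate added to gray-matter and background brain
#' voxels (not to the WM/CSF compartments, whose mean series act as
#' nuisance regressors: a global component that also loaded on them
#' would be removed by ordinary nuisance regression and the
#' with/without-GSReg contrast would vanish).
#'
#' @param dim_xyz Grid dimensions, e.g. `c(8, 8, 4)`.
#' @param n_volumes Number of time points.
#' @param tr Sampling interval, seconds. Default 2.
#' @param n_networks Number of planted networks. Default 2.
#' @param voxels_per_network Gray-matter voxels per network; scalar or
#'   one count per network. Default 20.
#' @param lags_s Per-network delay of the shared master source in seconds
#'   (`NA` = independent source). Default `c(0, 30)`: one reference
#'   network and one delayed ("anticorrelated"-type) network.
#' @param coupling Per-network coupling weight of the source in member
#'   voxels; a negative weight plants a negated ("anticorrelated at zero
#'   lag") copy. Default 1 for every network.
#' @param n_gm_null Gray-matter voxels carrying only noise (network 0);
#'   they give connectivity maps a null background. Default 20.
#' @param global_weight Weight of the additive global signal. Default 0.
#' @param noise_sd Standard deviation of voxelwise white noise relative to
#'   the unit-variance source. Default 0.5.
#' @param n_wm,n_csf Voxels in the WM and CSF compartments. Default 12.
#' @param seed Optional integer seed (byte-identical regeneration).
#' @param spec A [filter_spec()] for all band-limited sources.
#' @return An object of class `synth_fmri`: list with `bold` (4D array),
#'   `masks` (list of 3D logical arrays `gm`, `wm`, `csf`, `brain`),
#'   `atlas` (3D integer array, network labels on member voxels), `truth`
#'   (data frame: voxel coordinates, tissue, network, lag_s), `sources`
#'   (matrix of latent network sources), `global_signal`, `tr`, `config`.
#' @export
synth_fmri <- function(dim_xyz = c(8, 8, 4), n_volumes = 150L, tr = 2,
                       n_networks = 2L, voxels_per_network = 20L,
                       lags_s = c(0, 30), coupling = rep(1, n_networks),
                       global_weight = 0, noise_sd = 0.5, n_gm_null = 20L,
                       n_wm = 12L, n_csf = 12L, seed = NULL,
                       spec = filter_spec()) {
  check_tr(tr)
  stopifnot(length(dim_xyz) == 3L, all(dim_xyz >= 1L))
  if (length(lags_s) != n_networks)
    stop("`lags_s` must have one entry per network")
  if (length(coupling) != n_networks)
    stop("`coupling` must have one entry per network")
  nvox <- prod(dim_xyz)
  vpn <- rep_len(as.integer(voxels_per_network), n_networks)
  n_gm <- sum(vpn) + n_gm_null
  if (n_gm + n_wm + n_csf > nvox)
    stop("grid too small for the requested networks and tissue blocks")

  with_seed(seed, {
    master <- gen_surrogate(n_volumes, tr, NULL, spec)
    global_sig <- gen_surrogate(n_volumes, tr, NULL, spec)
    sources <- matrix(NA_real_, n_networks, n_volumes)
    for (k in seq_len(n_networks)) {
      if (is.na(lags_s[k])) {
        sources[k, ] <- gen_surrogate(n_volumes, tr, NULL, spec)
      } else {
        sh <- window_to_samples(abs(lags_s[k]), tr) %% n_volumes
        idx <- ((seq_len(n_volumes) - 1L - sign(lags_s[k]) * sh) %%
                  n_volumes) + 1L
        sources[k, ] <- master[idx]
      }
    }

    # voxel layout (linear order): networks, null GM, WM, CSF, rest bg
    tissue <- rep("bg", nvox)
    network <- rep(0L, nvox)
    pos <- 0L
    for (k in seq_len(n_networks)) {
      tissue[pos + seq_len(vpn[k])] <- "gm"
      network[pos + seq_len(vpn[k])] <- k
      pos <- pos + vpn[k]
    }
    if (n_gm_null > 0L) {
      tissue[pos + seq_len(n_gm_null)] <- "gm"
      pos <- pos + n_gm_null
    }
    tissue[pos + seq_len(n_wm)] <- "wm"
    pos <- pos + n_wm
    tissue[pos + seq_len(n_csf)] <- "csf"

    dat <- matrix(0, nvox, n_volumes)
    for (v in seq_len(nvox)) {
      base <- if (network[v] > 0L)
                coupling[network[v]] * sources[network[v], ]
              else numeric(n_volumes)
      gw <- if (tissue[v] %in% c("wm", "csf")) 0 else global_weight
      dat[v, ] <- base + noise_sd * rnorm(n_volumes) + gw * global_sig
    }

    coords <- arrayInd(seq_len(nvox), dim_xyz)
    truth <- data.frame(voxel = seq_len(nvox),
                        x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
                        tissue = tissue, network = network,
                        lag_s = ifelse(network > 0L, lags_s[pmax(network, 1L)],
                                       NA_real_))
    to3d <- function(v) array(v, dim_xyz)
    masks <- list(gm = to3d(tissue == "gm"),
                  wm = to3d(tissue == "wm"),
                  csf = to3d(tissue == "csf"),
                  brain = to3d(rep(TRUE, nvox)))
    atlas <- to3d(network)
    structure(list(bold = array(dat, c(dim_xyz, n_volumes)),
                   masks = masks, atlas = atlas, truth = truth,
                   sources = sources, global_signal = global_sig, tr = tr,
                   config = list(dim_xyz = dim_xyz, n_volumes = n_volumes,
                                 tr = tr, n_networks = n_networks,
                                 voxels_per_network = voxels_per_network,
                                 lags_s = lags_s, coupling = coupling,
                                 global_weight = global_weight,
                                 noise_sd = noise_sd, n_gm_null = n_gm_null,
                                 n_wm = n_wm, n_csf = n_csf, seed = seed)),
              class = "synth_fmri")
  })
}

#' @export
print.synth_fmri <- function(x, ...) {
  cat(sprintf(paste0("synthetic fMRI fixture: %s grid, %d volumes, ",
                     "%d network(s), global weight %.2f\n"),
              paste(x$config$dim_xyz, collapse = "x"), x$config$n_volumes,
              x$config$n_networks, x$config$global_weight))
  invisible(x)
}

#' Write a synthetic fixture to disk (NIfTI + TSV + JSON)
#'
#' Writes the 4D BOLD image, the binary masks, the integer-label atlas
#' (NIfTI-1 via RNifti), the ground-truth table (TSV) and the generating
#' configuration (JSON) into a directory.
#'
#' @param x A `synth_fmri` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synth_fmri <- function(x, dir) {
  stopifnot(inherits(x, "synth_fmri"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pix <- c(rep(3, 3), x$tr)  # 3 mm isotropic voxels, TR in seconds
  paths <- c(bold = file.path(dir, "bold.nii.gz"),
             gm = file.path(dir, "mask_gm.nii.gz"),
             wm = file.path(dir, "mask_wm.nii.gz"),
             csf = file.path(dir, "mask_csf.nii.gz"),
             brain = file.path(dir, "mask_brain.nii.gz"),
             atlas = file.path(dir, "atlas.nii.gz"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"))
  RNifti::writeNifti(RNifti::asNifti(x$bold, pixdim = pix), paths[["bold"]])
  for (m in c("gm", "wm", "csf", "brain"))
    RNifti::writeNifti(RNifti::asNifti(x$masks[[m]] * 1L), paths[[m]])
  RNifti::writeNifti(RNifti::asNifti(x$atlas), paths[["atlas"]])
  write.table(x$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(x$config, paths[["config"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
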