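# Plain-text and NIfTI I/O helpers shared by the command-line surface.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", check.names = FALSE)
}

#' Write a connectivity matrix (and its feature vector) as TSV
#'
#' @param m A `conn_matrix`.
#' @param matrix_path,features_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_conn_matrix <- function(m, matrix_path = NULL, features_path = NULL) {
  stopifnot(inherits(m, "conn_matrix"))
  if (!is.null(matrix_path)) {
    vals <- as.data.frame(m$values)
    vals <- cbind(roi = m$labels, vals)
    write_tsv(vals, matrix_path)
  }
  if (!is.null(features_path)) {
    fv <- matrix_to_features(m)
    write_tsv(data.frame(pair = names(fv), value = unname(fv)),
              features_path)
  }
  invisible(c(matrix_path, features_path))
}

#' Write a connectivity map as NIfTI volume(s)
#'
#' @param map A `conn_map`.
#' @param path Output path for the map values.
#' @param raw_path Optional output path for DTW raw distances.
#' @return Invisibly, the paths written.
#' @export
write_conn_map <- function(map, path, raw_path = NULL) {
  stopifnot(inherits(map, "conn_map"))
  vol <- map_volume(map, "values")
  vol[is.na(vol)] <- 0
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  if (!is.null(raw_path) && !is.null(map$raw)) {
    rv <- map_volume(map, "raw")
    rv[is.na(rv)] <- 0
    RNifti::writeNifti(RNifti::asNifti(rv), raw_path)
  }
  invisible(c(path, raw_path))
}

read_fixture <- function(dir) {
  nii <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing file: ", p)
    arr <- as.array(RNifti::readNifti(p))
    arr
  }
  cfg_path <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfg_path)) jsonlite::read_json(cfg_path,
                                                        simplifyVector = TRUE)
         else list()
  list(bold = nii("bold.nii.gz"),
       gm = nii("mask_gm.nii.gz") > 0,
       wm = nii("mask_wm.nii.gz") > 0,
       csf = nii("mask_csf.nii.gz") > 0,
       brain = nii("mask_brain.nii.gz") > 0,
       atlas = if (file.exists(file.path(dir, "atlas.nii.gz")))
                 nii("atlas.nii.gz") else NULL,
       config = cfg)
}
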