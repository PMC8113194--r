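#' Write and re-quantify phantom images on disk
#'
#' `write_spect_phantom()` writes the volume and VOI label map as NIfTI
#' files plus a JSON sidecar with the analytic truth indices;
#' `quantify_spect_files()` reads such a pair back and computes the DAT
#' indices from the images. `write_planar_pair()` / `quantify_planar_files()`
#' do the same for the early/delayed MIBG pair (2D NIfTI images; acquisition
#' times and half-life travel in the sidecar).
#'
#' @param phantom A `spect_phantom` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The written file paths (invisibly) for the writers; an index
#'   list (as from [extract_dat_indices()] / [extract_mibg_indices()]) for
#'   the quantifiers.
#' @export
write_spect_phantom <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "spect_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_volume.nii.gz", "_voi.nii.gz",
                                           "_truth.json")))
  pd <- rep(phantom$voxel_mm, 3)
  RNifti::writeNifti(RNifti::asNifti(phantom$volume, pixdim = pd), paths[1])
  RNifti::writeNifti(RNifti::asNifti(phantom$voi_map, pixdim = pd), paths[2])
  jsonlite::write_json(phantom$truth, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_spect_phantom
#' @param volume_file,voi_file Paths to the volume and VOI label-map NIfTI
#'   files.
#' @export
quantify_spect_files <- function(volume_file, voi_file) {
  vol <- as.array(RNifti::readNifti(volume_file))
  voi <- as.array(RNifti::readNifti(voi_file))
  storage.mode(voi) <- "integer"
  extract_dat_indices(striatal_counts(vol, voi))
}

#' @rdname write_spect_phantom
#' @param pair A `planar_pair` object.
#' @export
write_planar_pair <- function(pair, dir, prefix = "planar") {
  stopifnot(inherits(pair, "planar_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_early.nii.gz", "_delayed.nii.gz",
                                           "_roi.nii.gz", "_meta.json")))
  RNifti::writeNifti(RNifti::asNifti(pair$early_image), paths[1])
  RNifti::writeNifti(RNifti::asNifti(pair$delayed_image), paths[2])
  RNifti::writeNifti(RNifti::asNifti(pair$roi_map), paths[3])
  meta <- list(t_early = pair$t_early, t_delayed = pair$t_delayed,
               half_life = pair$half_life, truth = pair$truth)
  jsonlite::write_json(meta, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_spect_phantom
#' @param early_file,delayed_file,roi_file,meta_file Paths written by
#'   [write_planar_pair()].
#' @export
quantify_planar_files <- function(early_file, delayed_file, roi_file,
                                  meta_file) {
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  as_matrix <- function(f) {
    x <- as.array(RNifti::readNifti(f))
    matrix(x, dim(x)[1], dim(x)[2])
  }
  roi <- as_matrix(roi_file)
  storage.mode(roi) <- "integer"
  extract_mibg_indices(list(
    early_image = as_matrix(early_file),
    delayed_image = as_matrix(delayed_file),
    roi_map = roi,
    t_early = meta$t_early, t_delayed = meta$t_delayed,
    half_life = meta$half_life
  ))
}
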