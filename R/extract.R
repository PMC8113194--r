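#' VOI mean counts from a striatal SPECT volume
#'
#' Computes the mean voxel value (and voxel count) of each striatal VOI and
#' of the occipital reference VOI from a volume and its co-registered VOI
#' label map. Label codes follow [spect_voi_labels()].
#'
#' @param volume 3D numeric array of voxel intensities.
#' @param voi_map Integer array of the same dimensions with VOI labels.
#' @return An object of class `striatal_counts`: per-structure mean counts
#'   (`caudate_left`, `caudate_right`, `putamen_left`, `putamen_right`,
#'   `occipital`) and matching voxel counts in `n_voxels`.
#' @export
striatal_counts <- function(volume, voi_map) {
  if (!is.array(volume) || !is.array(voi_map) ||
      !identical(dim(volume), dim(voi_map)))
    stop_input("volume and voi_map must be arrays of identical dimensions")
  labels <- spect_voi_labels()
  means <- nvox <- numeric(0)
  for (s in names(labels)) {
    sel <- voi_map == labels[[s]]
    if (!any(sel)) stop_input("VOI '%s' is empty in the label map", s)
    means[[s]] <- mean(volume[sel])
    nvox[[s]] <- sum(sel)
  }
  out <- list(
    caudate_left = means[["left_caudate"]],
    caudate_right = means[["right_caudate"]],
    putamen_left = means[["left_putamen"]],
    putamen_right = means[["right_putamen"]],
    occipital = means[["occipital_reference"]],
    n_voxels = c(caudate_left = nvox[["left_caudate"]],
                 caudate_right = nvox[["right_caudate"]],
                 putamen_left = nvox[["left_putamen"]],
                 putamen_right = nvox[["right_putamen"]])
  )
  class(out) <- "striatal_counts"
  out
}

#' DAT SPECT indices from VOI mean counts
#'
#' Computes the three DAT SPECT indices from striatal VOI means. The
#' per-side striatal binding ratio uses the voxel-weighted mean of the
#' caudate and putamen VOIs on that side (the whole-striatum VOI union);
#' the reported SBR and PCR are the smaller of the two sides, and the
#' asymmetry index is computed from the two per-side SBRs.
#'
#' @param x A `striatal_counts` object (see [striatal_counts()]), a
#'   `spect_phantom`, or a list with fields `caudate_left`, `caudate_right`,
#'   `putamen_left`, `putamen_right`, `occipital` and optionally `n_voxels`
#'   (equal VOI sizes assumed when absent).
#' @return List with `sbr`, `pcr`, `ai`, the per-side values
#'   (`sbr_left`, `sbr_right`, `pcr_left`, `pcr_right`) and the sides
#'   selected by the minimum rule (`side_sbr`, `side_pcr`).
#' @export
#' @examples
#' ph <- generate_spect_phantom()
#' extract_dat_indices(ph)$sbr
extract_dat_indices <- function(x) {
  if (inherits(x, "spect_phantom")) x <- striatal_counts(x$volume, x$voi_map)
  need <- c("caudate_left", "caudate_right", "putamen_left", "putamen_right",
            "occipital")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop_input("striatal counts are missing fields: %s",
               paste(missing, collapse = ", "))
  nv <- x$n_voxels
  if (is.null(nv))
    nv <- c(caudate_left = 1, caudate_right = 1,
            putamen_left = 1, putamen_right = 1)
  union_mean <- function(side) {
    cs <- paste0("caudate_", side); ps <- paste0("putamen_", side)
    (nv[[cs]] * x[[cs]] + nv[[ps]] * x[[ps]]) / (nv[[cs]] + nv[[ps]])
  }
  sbr_left <- compute_sbr(union_mean("left"), x$occipital)
  sbr_right <- compute_sbr(union_mean("right"), x$occipital)
  pcr_left <- compute_pcr(x$putamen_left, x$caudate_left)
  pcr_right <- compute_pcr(x$putamen_right, x$caudate_right)
  list(
    sbr = min(sbr_left, sbr_right),
    pcr = min(pcr_left, pcr_right),
    ai = if ((sbr_left + sbr_right) / 2 > 0) {
      compute_ai(sbr_left, sbr_right)
    } else NA_real_,
    sbr_left = sbr_left, sbr_right = sbr_right,
    pcr_left = pcr_left, pcr_right = pcr_right,
    side_sbr = if (sbr_left <= sbr_right) "left" else "right",
    side_pcr = if (pcr_left <= pcr_right) "left" else "right"
  )
}

#' MIBG indices from an early/delayed planar pair
#'
#' Computes the heart-to-mediastinum count-density ratios on the early and
#' delayed images and the decay-corrected washout rate (percent). Count
#' density is the mean counts per pixel within the ROI; the decay
#' coefficient comes from the acquisition schedule and isotope half-life
#' via [decay_coefficient()].
#'
#' @param pair A `planar_pair` object, or a list with `early_image`,
#'   `delayed_image`, `roi_map`, `t_early`, `t_delayed`, `half_life`.
#' @return List with `hm_early`, `hm_delay`, `wr`, the decay coefficient
#'   `k`, and the per-image ROI densities in `densities`.
#' @export
extract_mibg_indices <- function(pair) {
  need <- c("early_image", "delayed_image", "roi_map",
            "t_early", "t_delayed", "half_life")
  missing <- setdiff(need, names(pair))
  if (length(missing))
    stop_input("planar pair is missing fields: %s",
               paste(missing, collapse = ", "))
  labels <- planar_roi_labels()
  roi_mean <- function(img, label_name) {
    sel <- pair$roi_map == labels[[label_name]]
    if (!any(sel)) stop_input("ROI '%s' is empty in the label map", label_name)
    mean(img[sel])
  }
  he <- roi_mean(pair$early_image, "heart")
  me <- roi_mean(pair$early_image, "mediastinum")
  hd <- roi_mean(pair$delayed_image, "heart")
  md <- roi_mean(pair$delayed_image, "mediastinum")
  k <- decay_coefficient(pair$t_early, pair$t_delayed, pair$half_life)
  list(
    hm_early = compute_hm(he, me),
    hm_delay = compute_hm(hd, md),
    wr = compute_wr(he, hd, me, md, k),
    k = k,
    densities = c(he = he, me = me, hd = hd, md = md)
  )
}
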