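#' Striatal binding ratio
#'
#' Ratio of the background-subtracted striatal VOI mean to the occipital
#' reference VOI mean, `(S - O) / O`. The occipital reference approximates
#' non-specific binding, so an SBR of 0 means no specific striatal uptake.
#' Note that some tools report the raw ratio `S / O`; this convention is the
#' raw ratio minus one.
#'
#' @param striatal_mean Mean counts of the striatal VOI (whole striatum,
#'   caudate plus putamen) on one side.
#' @param occipital_mean Mean counts of the occipital reference VOI;
#'   must be positive.
#' @return The striatal binding ratio (vectorized over inputs).
#' @export
#' @examples
#' compute_sbr(300, 100)  # 2.0
compute_sbr <- function(striatal_mean, occipital_mean) {
  if (!is.numeric(striatal_mean) || !is.numeric(occipital_mean))
    stop_input("striatal and occipital means must be numeric")
  if (any(!is.finite(occipital_mean)) || any(occipital_mean <= 0))
    stop_input("occipital reference mean must be positive")
  (striatal_mean - occipital_mean) / occipital_mean
}

#' Putamen-to-caudate ratio
#'
#' Ratio of the putamen VOI mean counts to the caudate VOI mean counts on
#' one side. Degeneration in Parkinsonian syndromes typically affects the
#' putamen first, lowering this ratio.
#'
#' @param putamen_mean Mean counts of the putamen VOI.
#' @param caudate_mean Mean counts of the caudate VOI; must be positive.
#' @return The putamen-to-caudate ratio (vectorized).
#' @export
compute_pcr <- function(putamen_mean, caudate_mean) {
  if (!is.numeric(putamen_mean) || !is.numeric(caudate_mean))
    stop_input("putamen and caudate means must be numeric")
  if (any(!is.finite(caudate_mean)) || any(caudate_mean <= 0))
    stop_input("caudate mean must be positive")
  putamen_mean / caudate_mean
}

#' Asymmetry index
#'
#' Absolute left-right difference in striatal binding ratio divided by the
#' mean of the two sides. Symmetric in its arguments; 0 for perfectly
#' symmetric uptake, on a fractional (not percent) scale.
#'
#' @param sbr_left,sbr_right Per-side striatal binding ratios.
#' @return The asymmetry index (vectorized).
#' @export
compute_ai <- function(sbr_left, sbr_right) {
  if (!is.numeric(sbr_left) || !is.numeric(sbr_right))
    stop_input("per-side SBR values must be numeric")
  m <- (sbr_left + sbr_right) / 2
  if (any(!is.finite(m)) || any(m <= 0))
    stop_input("mean of the two per-side SBR values must be positive")
  abs(sbr_left - sbr_right) / m
}

#' Heart-to-mediastinum ratio
#'
#' Count density (mean counts per pixel) of the cardiac ROI divided by that
#' of the mediastinal ROI, on an early or delayed planar MIBG image.
#'
#' @param heart_density Heart ROI count density.
#' @param mediastinum_density Mediastinal ROI count density; must be positive.
#' @return The H/M ratio (vectorized).
#' @export
compute_hm <- function(heart_density, mediastinum_density) {
  if (!is.numeric(heart_density) || !is.numeric(mediastinum_density))
    stop_input("count densities must be numeric")
  if (any(!is.finite(mediastinum_density)) || any(mediastinum_density <= 0))
    stop_input("mediastinal count density must be positive")
  heart_density / mediastinum_density
}

#' Physical-decay coefficient between two acquisitions
#'
#' Fraction of activity remaining at the delayed acquisition relative to the
#' early one, `2^(-(t_delayed - t_early) / half_life)`. Used to correct the
#' delayed MIBG counts for physical decay of the isotope before computing
#' the washout rate.
#'
#' @param t_early,t_delayed Acquisition times after injection, in hours;
#'   `t_delayed` must exceed `t_early`.
#' @param half_life Physical half-life of the isotope in hours. Defaults to
#'   iodine-123 (13.2232 h).
#' @return A number in (0, 1).
#' @export
#' @examples
#' decay_coefficient(0.25, 3)  # 15-min / 3-h schedule, I-123
decay_coefficient <- function(t_early, t_delayed, half_life = I123_HALF_LIFE_H) {
  if (!is_scalar_number(t_early) || !is_scalar_number(t_delayed))
    stop_input("acquisition times must be finite numbers")
  if (t_delayed <= t_early)
    stop_input("t_delayed (%g h) must exceed t_early (%g h)", t_delayed, t_early)
  if (!is_scalar_number(half_life) || half_life <= 0)
    stop_input("half_life must be a positive number of hours")
  2^(-(t_delayed - t_early) / half_life)
}

#' Cardiac MIBG washout rate
#'
#' Decay-corrected fractional loss of mediastinum-corrected cardiac counts
#' between the early and delayed images, in percent:
#' `100 * ((He - Me) - (Hd - Md) / k) / (He - Me)`,
#' where `He`/`Hd` are heart-ROI and `Me`/`Md` mediastinum-ROI count
#' densities on the early/delayed images and `k` is the physical-decay
#' coefficient (see [decay_coefficient()]). A washout rate of 0 means the
#' delayed image is the early image scaled by pure physical decay; 100 means
#' complete loss of mediastinum-corrected cardiac counts.
#'
#' @param he,hd Heart ROI count densities, early and delayed.
#' @param me,md Mediastinal ROI count densities, early and delayed.
#' @param k Decay coefficient in (0, 1].
#' @return Washout rate in percent.
#' @export
compute_wr <- function(he, hd, me, md, k) {
  for (v in list(he, hd, me, md)) {
    if (!is.numeric(v) || any(!is.finite(v)))
      stop_input("all count densities must be finite numbers")
  }
  if (!is.numeric(k) || any(k <= 0) || any(k > 1))
    stop_input("decay coefficient k must lie in (0, 1]")
  if (any(he <= me))
    stop_input("heart count density must exceed mediastinal density on the early image")
  100 * ((he - me) - (hd - md) / k) / (he - me)
}
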