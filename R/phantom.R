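# Label codes shared by the phantom generator and the VOI quantifier.
spect_voi_labels <- function() {
  c(left_caudate = 1L, right_caudate = 2L, left_putamen = 3L,
    right_putamen = 4L, occipital_reference = 5L)
}

planar_roi_labels <- function() {
  c(heart = 1L, mediastinum = 2L)
}

# Logical mask of an axis-aligned ellipsoid on a voxel grid.
ellipsoid_mask <- function(dim, center, semi_axes) {
  i <- slice.index(array(0, dim), 1)
  j <- slice.index(array(0, dim), 2)
  k <- slice.index(array(0, dim), 3)
  ((i - center[1]) / semi_axes[1])^2 +
    ((j - center[2]) / semi_axes[2])^2 +
    ((k - center[3]) / semi_axes[3])^2 <= 1
}

#' Generate a synthetic striatal SPECT phantom
#'
#' Builds a 3D volume on a fixed 64^3 grid (4.4 mm isotropic voxels) with
#' parametric caudate and putamen ellipsoids on both sides, a cuboid
#' occipital reference slab and a uniform background, plus the matching VOI
#' label map. The uptake configured for each structure is the exact
#' noise-free voxel value inside it, so the quantitative indices implied by
#' the configuration are known analytically and are returned as `truth`.
#' This is a quantification fixture, not a physical simulation: no
#' attenuation, scatter or resolution modelling.
#'
#' @param uptake Named vector of mean voxel intensities for
#'   `left_caudate`, `right_caudate`, `left_putamen`, `right_putamen`,
#'   `occipital_reference` and optionally `background` (default 2).
#'   The occipital uptake must be positive.
#' @param noise_sd Standard deviation of additive Gaussian voxel noise
#'   (clipped at zero); 0 gives a noise-free phantom.
#' @param seed Integer seed for the noise.
#' @param poisson If `TRUE`, voxel values are Poisson counts with the
#'   configured uptake as mean (applied before the Gaussian noise).
#' @return An object of class `spect_phantom`: list with `volume` (64^3
#'   array), `voi_map` (integer array, labels per [spect_voi_labels()]),
#'   `voxel_mm`, `uptake` and `truth` (analytic `sbr`, `pcr`, `ai`,
#'   per-side values and the sides the minimum rule selected).
#' @export
#' @examples
#' ph <- generate_spect_phantom()
#' ph$truth$sbr
generate_spect_phantom <- function(uptake = c(left_caudate = 260,
                                              right_caudate = 255,
                                              left_putamen = 210,
                                              right_putamen = 220,
                                              occipital_reference = 100),
                                   noise_sd = 0, seed = 1L,
                                   poisson = FALSE) {
  labels <- spect_voi_labels()
  need <- names(labels)
  missing <- setdiff(need, names(uptake))
  if (length(missing))
    stop_input("uptake is missing structures: %s", paste(missing, collapse = ", "))
  if (!is.numeric(uptake) || any(!is.finite(uptake)))
    stop_input("uptake values must be finite numbers")
  if (uptake[["occipital_reference"]] <= 0)
    stop_input("occipital reference uptake must be positive")
  background <- if ("background" %in% names(uptake)) uptake[["background"]] else 2
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    stop_input("noise_sd must be a non-negative number")

  dim3 <- c(64L, 64L, 64L)
  # Anterior = larger j; striata mid-volume, occipital slab posterior.
  masks <- list(
    left_caudate = ellipsoid_mask(dim3, c(25, 40, 32), c(2.6, 3.6, 3.0)),
    right_caudate = ellipsoid_mask(dim3, c(40, 40, 32), c(2.6, 3.6, 3.0)),
    left_putamen = ellipsoid_mask(dim3, c(22, 32, 32), c(2.8, 4.8, 3.2)),
    right_putamen = ellipsoid_mask(dim3, c(43, 32, 32), c(2.8, 4.8, 3.2)),
    occipital_reference = {
      m <- array(FALSE, dim3)
      m[20:45, 6:12, 26:38] <- TRUE
      m
    }
  )
  overlap <- Reduce(`+`, lapply(masks, as.integer))
  if (any(overlap > 1)) stop("internal error: overlapping phantom structures")

  volume <- array(background, dim3)
  voi_map <- array(0L, dim3)
  for (s in need) {
    volume[masks[[s]]] <- uptake[[s]]
    voi_map[masks[[s]]] <- labels[[s]]
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  if (poisson) volume[] <- stats::rpois(length(volume), volume)
  if (noise_sd > 0)
    volume[] <- pmax(volume + stats::rnorm(length(volume), 0, noise_sd), 0)

  nv <- vapply(masks, sum, integer(1))
  occ <- uptake[["occipital_reference"]]
  striatal_union <- function(side) {
    cs <- paste0(side, "_caudate"); ps <- paste0(side, "_putamen")
    (nv[[cs]] * uptake[[cs]] + nv[[ps]] * uptake[[ps]]) / (nv[[cs]] + nv[[ps]])
  }
  sbr_left <- compute_sbr(striatal_union("left"), occ)
  sbr_right <- compute_sbr(striatal_union("right"), occ)
  pcr_left <- compute_pcr(uptake[["left_putamen"]], uptake[["left_caudate"]])
  pcr_right <- compute_pcr(uptake[["right_putamen"]], uptake[["right_caudate"]])
  truth <- list(
    sbr_left = sbr_left, sbr_right = sbr_right,
    pcr_left = pcr_left, pcr_right = pcr_right,
    sbr = min(sbr_left, sbr_right),
    pcr = min(pcr_left, pcr_right),
    # AI undefined (flagged NA) when there is no net specific uptake
    ai = if ((sbr_left + sbr_right) / 2 > 0) {
      compute_ai(sbr_left, sbr_right)
    } else NA_real_,
    side_sbr = if (sbr_left <= sbr_right) "left" else "right",
    side_pcr = if (pcr_left <= pcr_right) "left" else "right"
  )

  structure(list(volume = volume, voi_map = voi_map, voxel_mm = 4.4,
                 uptake = uptake, noise_sd = noise_sd, truth = truth),
            class = "spect_phantom")
}

#' Generate a synthetic early/delayed planar MIBG image pair
#'
#' Builds paired 2D planar chest images (128 x 128) with a circular cardiac
#' ROI and a rectangular mediastinal ROI at fixed positions, uniform
#' configured count densities inside each ROI on each image, and a uniform
#' background. The heart-to-mediastinum ratios and the washout rate implied
#' by the configuration are computed analytically and returned as `truth`.
#'
#' @param heart_early,mediastinum_early Count densities on the early image;
#'   heart must exceed mediastinum.
#' @param heart_delayed,mediastinum_delayed Count densities on the delayed
#'   image.
#' @param t_early,t_delayed Acquisition times post-injection in hours
#'   (defaults: 15 min and 3 h).
#' @param half_life Isotope half-life in hours (default iodine-123).
#' @param noise_sd Additive Gaussian pixel noise SD (clipped at zero).
#' @param seed Integer seed for the noise.
#' @param background Background count density (default 1).
#' @return An object of class `planar_pair`: list with `early_image`,
#'   `delayed_image`, `roi_map` (labels per [planar_roi_labels()]),
#'   `t_early`, `t_delayed`, `half_life` and `truth`
#'   (`hm_early`, `hm_delay`, `wr`, `k`).
#' @export
generate_planar_pair <- function(heart_early = 180, mediastinum_early = 70,
                                 heart_delayed = 120, mediastinum_delayed = 60,
                                 t_early = 0.25, t_delayed = 3,
                                 half_life = I123_HALF_LIFE_H,
                                 noise_sd = 0, seed = 1L, background = 1) {
  vals <- c(heart_early, mediastinum_early, heart_delayed, mediastinum_delayed)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_input("all ROI count densities must be positive")
  if (heart_early <= mediastinum_early)
    stop_input("early heart density must exceed early mediastinal density")
  if (t_delayed <= t_early)
    stop_input("t_delayed must exceed t_early")
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    stop_input("noise_sd must be a non-negative number")

  dim2 <- c(128L, 128L)
  ij <- expand.grid(i = seq_len(dim2[1]), j = seq_len(dim2[2]))
  heart_mask <- matrix((ij$i - 74)^2 + (ij$j - 58)^2 <= 14^2, dim2[1], dim2[2])
  med_mask <- matrix(ij$i >= 58 & ij$i <= 70 & ij$j >= 86 & ij$j <= 110,
                     dim2[1], dim2[2])
  if (any(heart_mask & med_mask)) stop("internal error: overlapping ROIs")

  roi_map <- matrix(0L, dim2[1], dim2[2])
  roi_map[heart_mask] <- planar_roi_labels()[["heart"]]
  roi_map[med_mask] <- planar_roi_labels()[["mediastinum"]]

  make_image <- function(heart, med) {
    img <- matrix(background, dim2[1], dim2[2])
    img[heart_mask] <- heart
    img[med_mask] <- med
    img
  }
  early <- make_image(heart_early, mediastinum_early)
  delayed <- make_image(heart_delayed, mediastinum_delayed)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  if (noise_sd > 0) {
    early[] <- pmax(early + stats::rnorm(length(early), 0, noise_sd), 0)
    delayed[] <- pmax(delayed + stats::rnorm(length(delayed), 0, noise_sd), 0)
  }

  k <- decay_coefficient(t_early, t_delayed, half_life)
  truth <- list(
    hm_early = compute_hm(heart_early, mediastinum_early),
    hm_delay = compute_hm(heart_delayed, mediastinum_delayed),
    wr = compute_wr(heart_early, heart_delayed,
                    mediastinum_early, mediastinum_delayed, k),
    k = k
  )

  structure(list(early_image = early, delayed_image = delayed,
                 roi_map = roi_map, t_early = t_early, t_delayed = t_delayed,
                 half_life = half_life, noise_sd = noise_sd, truth = truth),
            class = "planar_pair")
}
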