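test_that("noise-free phantoms carry non-empty VOIs and analytic truth", {
  ph <- generate_spect_phantom()
  labels <- parkcart:::spect_voi_labels()
  for (s in names(labels)) {
    expect_gt(sum(ph$voi_map == labels[[s]]), 0)
  }
  expect_identical(dim(ph$volume), c(64L, 64L, 64L))
  expect_equal(ph$voxel_mm, 4.4)
  # truth recomputable from the configured uptakes
  occ <- ph$uptake[["occipital_reference"]]
  nv <- sapply(names(labels), function(s) sum(ph$voi_map == labels[[s]]))
  left_union <- (nv[["left_caudate"]] * ph$uptake[["left_caudate"]] +
                   nv[["left_putamen"]] * ph$uptake[["left_putamen"]]) /
    (nv[["left_caudate"]] + nv[["left_putamen"]])
  expect_equal(ph$truth$sbr_left, (left_union - occ) / occ)
})

test_that("quantifying a noise-free phantom reproduces truth to 1e-9", {
  ph <- generate_spect_phantom(uptake = c(left_caudate = 182.3,
                                          right_caudate = 241.7,
                                          left_putamen = 133.9,
                                          right_putamen = 201.2,
                                          occipital_reference = 87.5))
  q <- extract_dat_indices(ph)
  for (f in c("sbr", "pcr", "ai", "sbr_left", "sbr_right")) {
    expect_lt(abs(q[[f]] - ph$truth[[f]]) / max(abs(ph$truth[[f]]), 1),
              1e-9)
  }
  expect_identical(q$side_sbr, ph$truth$side_sbr)
})

test_that("flat and symmetric uptake configurations hit the identities", {
  flat <- generate_spect_phantom(uptake = c(left_caudate = 100,
                                            right_caudate = 100,
                                            left_putamen = 100,
                                            right_putamen = 100,
                                            occipital_reference = 100))
  expect_equal(flat$truth$sbr_left, 0)
  expect_equal(flat$truth$sbr_right, 0)
  expect_true(is.na(flat$truth$ai))  # no net uptake: asymmetry undefined
  sym <- generate_spect_phantom(uptake = c(left_caudate = 150,
                                           right_caudate = 180,
                                           left_putamen = 150,
                                           right_putamen = 180,
                                           occipital_reference = 90))
  expect_equal(sym$truth$pcr_left, 1)
  expect_equal(sym$truth$pcr_right, 1)
  expect_equal(sym$truth$ai,
               compute_ai(sym$truth$sbr_left, sym$truth$sbr_right))
  expect_error(generate_spect_phantom(uptake = c(left_caudate = 1,
                                                 right_caudate = 1,
                                                 left_putamen = 1,
                                                 right_putamen = 1,
                                                 occipital_reference = 0)),
               "occipital")
})

test_that("a planted per-side SBR round-trips through the image path", {
  # choose uptakes so the left whole-striatum SBR is exactly 1.65
  occ <- 100
  ph0 <- generate_spect_phantom()
  nv <- sapply(names(parkcart:::spect_voi_labels()),
               function(s) sum(ph0$voi_map == parkcart:::spect_voi_labels()[[s]]))
  ncl <- nv[["left_caudate"]]; npl <- nv[["left_putamen"]]
  target_union <- occ * (1 + 1.65)
  pl <- 240
  cl <- (target_union * (ncl + npl) - npl * pl) / ncl
  ph <- generate_spect_phantom(uptake = c(left_caudate = cl,
                                          right_caudate = 300,
                                          left_putamen = pl,
                                          right_putamen = 290,
                                          occipital_reference = occ))
  q <- extract_dat_indices(ph)
  expect_lt(abs(q$sbr - 1.65), 1e-9)
  expect_identical(q$side_sbr, "left")
})

test_that("phantom noise is seeded, reproducible and clipped", {
  a <- generate_spect_phantom(noise_sd = 5, seed = 21)
  b <- generate_spect_phantom(noise_sd = 5, seed = 21)
  c <- generate_spect_phantom(noise_sd = 5, seed = 22)
  expect_identical(a$volume, b$volume)
  expect_false(identical(a$volume, c$volume))
  expect_true(all(a$volume >= 0))
})

test_that("planar pairs embed exact analytic truth and validate input", {
  pp <- generate_planar_pair(heart_early = 180, mediastinum_early = 70,
                             heart_delayed = 120, mediastinum_delayed = 60)
  m <- extract_mibg_indices(pp)
  expect_lt(abs(m$hm_early - pp$truth$hm_early), 1e-9)
  expect_lt(abs(m$hm_delay - pp$truth$hm_delay), 1e-9)
  expect_lt(abs(m$wr - pp$truth$wr) / abs(pp$truth$wr), 1e-9)
  # equal heart and mediastinum: both ratios 1 (wr undefined, He = Me)
  expect_error(generate_planar_pair(heart_early = 50,
                                    mediastinum_early = 50),
               "exceed")
  eq <- list(hm_early = compute_hm(70, 70), hm_delay = compute_hm(50, 50))
  expect_equal(eq$hm_early, 1)
  expect_equal(eq$hm_delay, 1)
  # delayed = early scaled by k: zero washout
  k <- decay_coefficient(0.25, 3)
  pd <- generate_planar_pair(heart_early = 180, mediastinum_early = 70,
                             heart_delayed = 180 * k,
                             mediastinum_delayed = 70 * k)
  expect_lt(abs(pd$truth$wr), 1e-9)
  expect_error(generate_planar_pair(t_early = 3, t_delayed = 0.25),
               "exceed")
})

test_that("random positive planar configurations round-trip exactly", {
  set.seed(13)
  for (i in 1:10) {
    me <- runif(1, 20, 60)
    he <- me + runif(1, 5, 100)
    pp <- generate_planar_pair(heart_early = he, mediastinum_early = me,
                               heart_delayed = runif(1, 10, 150),
                               mediastinum_delayed = runif(1, 5, 80))
    m <- extract_mibg_indices(pp)
    expect_lt(abs(m$wr - pp$truth$wr) / max(abs(pp$truth$wr), 1), 1e-9)
    expect_lt(abs(m$hm_early - pp$truth$hm_early), 1e-9)
  }
})

test_that("phantom and planar NIfTI files round-trip the indices", {
  dir <- withr::local_tempdir()
  ph <- generate_spect_phantom()
  paths <- write_spect_phantom(ph, dir)
  q <- quantify_spect_files(paths[1], paths[2])
  expect_lt(abs(q$sbr - ph$truth$sbr), 1e-6)
  expect_lt(abs(q$pcr - ph$truth$pcr), 1e-6)
  truth <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  expect_equal(truth$sbr, ph$truth$sbr)

  pp <- generate_planar_pair()
  pf <- write_planar_pair(pp, dir)
  m <- quantify_planar_files(pf[1], pf[2], pf[3], pf[4])
  expect_lt(abs(m$wr - pp$truth$wr), 1e-6)
  expect_lt(abs(m$hm_delay - pp$truth$hm_delay), 1e-6)
})
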