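test_that("an unblurred disc has essentially no brightened halo", {
  for (fov in c(300, 150)) {
    spec <- phantom_spec("concentric_disc", 6, 1000, psf_sigma_mm = 0,
                         supersampling = 1L, fov_mm = fov)
    bm <- measure_bloom(render_scene(spec))
    expect_lte(bm$adjacent_affected_mm, fov / 512)
  }
  # halo shrinks with pixel size when there is no blur
  coarse <- measure_bloom(render_scene(
    phantom_spec("concentric_disc", 6, 1000, 0, supersampling = 1L,
                 fov_mm = 300)))$adjacent_affected_mm
  fine <- measure_bloom(render_scene(
    phantom_spec("concentric_disc", 6, 1000, 0, supersampling = 1L,
                 fov_mm = 300, matrix_size = 2048)))$adjacent_affected_mm
  expect_lt(fine, coarse)
})

test_that("the measured halo matches the continuum crossing distance", {
  spec <- phantom_spec("concentric_disc", 6, 1404, psf_sigma_mm = 0.5,
                       fov_mm = 150)
  bm <- measure_bloom(render_scene(spec))
  expect_equal(bm$adjacent_affected_mm, cont_halo(spec), tolerance = 0.05 / cont_halo(spec))
  # all four directions clean and symmetric
  expect_false(any(nzchar(bm$flags)))
  expect_lt(diff(range(bm$per_direction_halo_mm)), 0.06)
})

test_that("a direction blocked by a contrast lumen is flagged and contributes zero", {
  spec <- phantom_spec("concentric_disc", 6, 2000, psf_sigma_mm = 0.5,
                       contrast_lumen = list(lumen_hu = 400,
                                             lumen_diameter_mm = 4))
  bm <- measure_bloom(render_scene(spec))
  expect_true(nzchar(bm$flags[["right"]]))
  expect_identical(bm$per_direction_halo_mm[["right"]], 0)
  expect_false(any(nzchar(bm$flags[c("up", "down", "left")])))
  # the adjacent metric is still the mean over all four directions
  expect_equal(bm$adjacent_affected_mm, mean(bm$per_direction_halo_mm))
})

test_that("measurements are invariant under amplitude scaling", {
  spec <- phantom_spec("concentric_disc", 5, 1000, psf_sigma_mm = 0.5)
  g <- render_scene(spec)
  b0 <- measure_bloom(g)
  for (peak in default_energy_ladder()$peak_hu) {
    gs <- image_grid(g$pixels * (peak / 1000), g$pixel_spacing_mm)
    bs <- measure_bloom(gs)
    expect_lt(abs(bs$adjacent_affected_mm - b0$adjacent_affected_mm), 1e-9)
    expect_lt(abs(bs$length_actual_mm - b0$length_actual_mm), 1e-9)
    expect_lt(abs(bs$length_brightened_mm - b0$length_brightened_mm), 1e-9)
  }
})

test_that("bloom bookkeeping is internally consistent", {
  spec <- phantom_spec("concentric_disc", 6, 1404, psf_sigma_mm = 0.5)
  bm <- measure_bloom(render_scene(spec))
  expect_equal(bm$length_brightened_mm - bm$length_actual_mm,
               bm$adjacent_affected_mm, tolerance = 1e-12)
  expect_true(all(bm$per_direction_halo_mm >= 0))
  expect_equal(bm$adjacent_affected_px,
               bm$adjacent_affected_mm / (300 / 512), tolerance = 1e-12)
  expect_equal(bm$length_actual_mm,
               (bm$length_actual_h_mm + bm$length_actual_v_mm) / 2)
})

test_that("halving the pixel size changes the halo by less than one coarse pixel", {
  for (sigma in c(0.4, 0.5)) {
    s300 <- phantom_spec("concentric_disc", 6, 1404, psf_sigma_mm = sigma,
                         fov_mm = 300)
    s150 <- phantom_spec("concentric_disc", 6, 1404, psf_sigma_mm = sigma,
                         fov_mm = 150)
    a300 <- measure_bloom(render_scene(s300))$adjacent_affected_mm
    a150 <- measure_bloom(render_scene(s150))$adjacent_affected_mm
    expect_lt(abs(a300 - a150), 300 / 512)
  }
})

test_that("FW3M recovers the true diameter up to the predictable threshold bias", {
  # narrow PSF: recovery within max(0.3 mm, pixel spacing)
  for (D in c(4, 5, 6)) {
    spec <- phantom_spec("concentric_disc", D, 1404, psf_sigma_mm = 0.3,
                         fov_mm = 150)
    bm <- measure_bloom(render_scene(spec))
    expect_lt(abs(bm$length_actual_mm - D), max(0.3, 150 / 512))
  }
  # wider PSF: the FW3M overshoot equals the continuum threshold bias
  for (sigma in c(0.4, 0.5)) {
    spec <- phantom_spec("concentric_disc", 5, 1404, psf_sigma_mm = sigma,
                         fov_mm = 150)
    bm <- measure_bloom(render_scene(spec))
    expect_equal(bm$length_actual_mm - 5, cont_width(spec, 1 / 3) - 5,
                 tolerance = 0.05 / (cont_width(spec, 1 / 3) - 5))
  }
})

test_that("FW3M/FWHM error summary behaves as the blur model predicts", {
  # no blur: both methods limited only by pixelation
  res0 <- fw3m_vs_fwhm_error(peak_hus = c(1000, 2000), psf_sigma_mm = 0,
                             supersampling = 1L, fov_mm = 150)
  expect_lt(res0$mean_error_mm[res0$method == "FW3M"], 150 / 512)
  expect_lt(res0$mean_error_mm[res0$method == "FWHM"], 150 / 512)

  # plateau-reaching Gaussian blur: FWHM nearly exact, FW3M biased upward
  res <- fw3m_vs_fwhm_error(peak_hus = c(1404, 871), psf_sigma_mm = 0.3,
                            fov_mm = 150)
  e_fwhm <- res$mean_error_mm[res$method == "FWHM"]
  e_fw3m <- res$mean_error_mm[res$method == "FW3M"]
  expect_lt(e_fwhm, 0.05)
  expect_gt(e_fw3m, 0.1)
  # errors match continuum re-measurement of the same scenes
  cont_err <- mean(vapply(c(4, 5, 6), function(D)
    cont_width(phantom_spec("concentric_disc", D, 1404, psf_sigma_mm = 0.3,
                            fov_mm = 150), 1 / 3) - D, numeric(1)))
  expect_equal(e_fw3m, cont_err, tolerance = 0.05 / cont_err)
})
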