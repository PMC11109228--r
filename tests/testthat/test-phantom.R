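test_that("unblurred rendering assigns peak to pixels whose centres fall inside the disc", {
  spec <- phantom_spec("concentric_disc", 6, 1000, psf_sigma_mm = 0,
                       supersampling = 1L, fov_mm = 300, matrix_size = 512)
  g <- render_scene(spec)
  expect_setequal(unique(as.vector(g$pixels)), c(0, 1000))
  sp <- 300 / 512
  cc <- (seq_len(512) - 0.5) * sp
  inside <- outer((cc - 150)^2, (cc - 150)^2, "+") <= 9
  expect_identical(g$pixels == 1000, inside)
})

test_that("amplitudes above the HU ceiling are clipped", {
  spec <- phantom_spec("concentric_disc", 6, 4000, psf_sigma_mm = 0,
                       supersampling = 1L)
  g <- render_scene(spec)
  expect_identical(max(g$pixels), 3071)
  expect_setequal(unique(as.vector(g$pixels)), c(0, 3071))
})

test_that("closed-form blurred-disc profile matches brute-force quadrature", {
  spec <- phantom_spec("concentric_disc", 6, 1404, psf_sigma_mm = 0.5)
  radii <- seq(0, 5, by = 0.25)
  brute <- vapply(radii, function(r) brute_blurred_disc(1404, 6, 0.5, r),
                  numeric(1))
  expect_lt(max(abs(analytic_profile(spec, radii) - brute)), 0.1)
  # plateau limit and edge value for a narrow PSF
  narrow <- phantom_spec("concentric_disc", 6, 1404, psf_sigma_mm = 0.1)
  expect_equal(analytic_profile(narrow, 0), 1404, tolerance = 1e-6)
  expect_equal(analytic_profile(narrow, 3), 1404 / 2, tolerance = 0.02)
  expect_error(analytic_profile(
    phantom_spec("stent_like", 6, 1000), 0), "concentric")
})

test_that("rendered central row tracks the pixel-averaged continuum field", {
  spec16 <- phantom_spec("concentric_disc", 6, 1404, psf_sigma_mm = 0.5,
                         supersampling = 16L)
  g16 <- render_scene(spec16)
  row16 <- extract_profile(g16, c(150, 150), "full_horizontal")$values_hu
  err16 <- max(abs(row16 - box_avg_center_row(spec16)))
  expect_lt(err16, 1.5)
  # finer rasterization converges toward the continuum
  spec32 <- phantom_spec("concentric_disc", 6, 1404, psf_sigma_mm = 0.5,
                         supersampling = 32L)
  g32 <- render_scene(spec32)
  row32 <- extract_profile(g32, c(150, 150), "full_horizontal")$values_hu
  expect_lt(max(abs(row32 - box_avg_center_row(spec32))), err16)
})

test_that("integrated attenuation is conserved by rasterization and blur", {
  for (sigma in c(0, 0.5)) {
    spec <- phantom_spec("concentric_disc", 6, 1404, psf_sigma_mm = sigma,
                         supersampling = 16L)
    g <- render_scene(spec)
    total <- sum(g$pixels) * (300 / 512)^2
    expect_lt(abs(total - 1404 * pi * 9) / (1404 * pi * 9), 0.01)
  }
})

test_that("noise-free unclipped grids scale linearly in the peak amplitude", {
  s1 <- phantom_spec("concentric_disc", 5, 800, psf_sigma_mm = 0.4)
  s2 <- phantom_spec("concentric_disc", 5, 2000, psf_sigma_mm = 0.4)
  g1 <- render_scene(s1)$pixels
  g2 <- render_scene(s2)$pixels
  expect_lt(max(abs(g2 - g1 * 2000 / 800)), 1e-9 * 2000)
})

test_that("raising the HU ceiling never decreases a pixel", {
  lo <- render_scene(phantom_spec("concentric_disc", 6, 4000,
                                  psf_sigma_mm = 0.5, hu_ceiling = 2000))
  hi <- render_scene(phantom_spec("concentric_disc", 6, 4000,
                                  psf_sigma_mm = 0.5, hu_ceiling = 3071))
  expect_true(all(hi$pixels >= lo$pixels))
})

test_that("identical spec and seed reproduce the grid bit-for-bit", {
  spec <- phantom_spec("concentric_disc", 5, 1404, psf_sigma_mm = 0.5,
                       noise_sd_hu = 7.33, seed = 42L)
  expect_identical(render_scene(spec)$pixels, render_scene(spec)$pixels)
})

test_that("energy series shares geometry: grids are scalar multiples unless clipped", {
  spec <- phantom_spec("concentric_disc", 6, 1404, psf_sigma_mm = 0.5)
  et <- default_energy_ladder()
  et$noise_sd_hu <- 0
  grids <- render_energy_series(spec, et)
  base <- grids[[2]]$pixels / et$peak_hu[2]
  for (l in seq_len(nrow(et))) {
    scaled <- pmin(base * et$peak_hu[l], 3071)
    expect_lt(max(abs(grids[[l]]$pixels - scaled)), 1e-9 * et$peak_hu[l])
  }
  expect_identical(grids[[1]]$energy_label, "40keV")
  # identical peaks -> identical noise-free grids
  et2 <- data.frame(energy_label = c("a", "b"), peak_hu = c(1000, 1000),
                    noise_sd_hu = 0)
  g2 <- render_energy_series(spec, et2)
  expect_identical(g2[[1]]$pixels, g2[[2]]$pixels)
  # polychromatic ladder: maxima decrease monotonically with energy
  gk <- render_energy_series(spec, transform(default_kvp_ladder(),
                                             noise_sd_hu = 0))
  maxima <- vapply(gk, function(g) max(g$pixels), numeric(1))
  expect_true(all(diff(maxima) < 0))
  expect_error(render_energy_series(spec, data.frame()), "empty")
})

test_that("invalid specs and oversized PSF kernels are rejected", {
  expect_error(phantom_spec("concentric_disc", -1, 1000), "positive")
  expect_error(phantom_spec("concentric_disc", 400, 1000, fov_mm = 300),
               "smaller than")
  expect_error(phantom_spec("concentric_disc", 6, 0), "positive")
  expect_error(phantom_spec("concentric_disc", 6, 1000, psf_sigma_mm = -1))
  expect_error(phantom_spec("concentric_disc", 6, 1000,
                            contrast_lumen = list(lumen_hu = 2000,
                                                  lumen_diameter_mm = 2)),
               "lumen_hu")
  big <- phantom_spec("concentric_disc", 6, 1000, psf_sigma_mm = 8,
                      fov_mm = 30, matrix_size = 16, supersampling = 1L)
  expect_error(render_scene(big), "kernel")
})

test_that("contrast lumen adds to the scene before clipping", {
  spec <- phantom_spec("concentric_disc", 6, 2000, psf_sigma_mm = 0,
                       supersampling = 1L,
                       contrast_lumen = list(lumen_hu = 400,
                                             lumen_diameter_mm = 4))
  g <- render_scene(spec)
  expect_setequal(unique(as.vector(g$pixels)), c(0, 400, 2000))
  # overlapping lumen sums with the calcification
  spec2 <- phantom_spec("concentric_disc", 6, 2000, psf_sigma_mm = 0,
                        supersampling = 1L,
                        contrast_lumen = list(lumen_hu = 400,
                                              lumen_diameter_mm = 4,
                                              offset_mm = 3))
  expect_identical(max(render_scene(spec2)$pixels), 2400)
})
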