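#' Parametric description of a synthetic calcification scene
#'
#' Describes a digital calcification phantom: a high-attenuation shape on a
#' 0 HU background, blurred by an isotropic Gaussian point-spread function to
#' emulate the peri-calcific blooming halo, with partial-volume averaging
#' (supersampled rasterization), additive Gaussian noise, and clipping to the
#' scanner's representable HU range.
#'
#' @param shape_kind one of `"concentric_disc"` (full disc), `"eccentric_disc"`
#'   (circular segment: a disc with a chord cut at half the radius), or
#'   `"stent_like"` (annulus of outer diameter `diameter_mm` and wall
#'   `wall_thickness_mm`).
#' @param diameter_mm calcification diameter (outer diameter for stents), mm.
#' @param peak_hu attenuation amplitude of the calcification, HU (> 0).
#' @param psf_sigma_mm standard deviation of the Gaussian PSF, mm (>= 0).
#' @param noise_sd_hu additive zero-mean Gaussian noise SD, HU (>= 0).
#' @param fov_mm field of view, mm; pixel spacing is `fov_mm / matrix_size`.
#' @param matrix_size pixels per side of the reconstructed grid.
#' @param supersampling integer antialias factor; each pixel is the mean of
#'   `supersampling^2` sub-samples (partial-volume model).
#' @param hu_ceiling,hu_floor clip limits applied after noise (12-bit clinical
#'   default ceiling 3071 HU).
#' @param wall_thickness_mm stent wall thickness, mm (stent_like only).
#' @param contrast_lumen optional list `(lumen_hu, lumen_diameter_mm,
#'   offset_mm)` adding a contrast-agent disc centred `offset_mm` to the right
#'   of the calcification centre (default offset: abutting edges). Amplitudes
#'   add before clipping.
#' @param seed RNG seed for the noise stream (NULL = current stream).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_kind = c("concentric_disc", "eccentric_disc", "stent_like"),
                         diameter_mm, peak_hu, psf_sigma_mm = 0.5,
                         noise_sd_hu = 0, fov_mm = 300, matrix_size = 512,
                         supersampling = 16L, hu_ceiling = 3071,
                         hu_floor = -1024, wall_thickness_mm = 1,
                         contrast_lumen = NULL, seed = NULL) {
  shape_kind <- match.arg(shape_kind)
  for (nm in c("diameter_mm", "peak_hu", "psf_sigma_mm", "noise_sd_hu",
               "fov_mm", "matrix_size", "supersampling"))
    if (!is_scalar_num(get(nm))) stopf("`%s` must be a finite numeric scalar", nm)
  if (diameter_mm <= 0) stopf("`diameter_mm` must be positive")
  if (diameter_mm >= fov_mm) stopf("`diameter_mm` must be smaller than `fov_mm`")
  if (peak_hu <= 0) stopf("`peak_hu` must be positive")
  if (psf_sigma_mm < 0) stopf("`psf_sigma_mm` must be >= 0")
  if (noise_sd_hu < 0) stopf("`noise_sd_hu` must be >= 0")
  if (matrix_size < 8 || matrix_size != round(matrix_size))
    stopf("`matrix_size` must be an integer >= 8")
  if (supersampling < 1 || supersampling != round(supersampling))
    stopf("`supersampling` must be an integer >= 1")
  if (hu_ceiling <= hu_floor) stopf("`hu_ceiling` must exceed `hu_floor`")
  if (shape_kind == "stent_like" &&
      (!is_scalar_num(wall_thickness_mm) || wall_thickness_mm <= 0 ||
       wall_thickness_mm >= diameter_mm / 2))
    stopf("`wall_thickness_mm` must lie in (0, diameter_mm/2)")
  if (!is.null(contrast_lumen)) {
    need <- c("lumen_hu", "lumen_diameter_mm")
    if (!is.list(contrast_lumen) || !all(need %in% names(contrast_lumen)))
      stopf("`contrast_lumen` needs fields lumen_hu and lumen_diameter_mm")
    if (contrast_lumen$lumen_hu <= 0 || contrast_lumen$lumen_hu >= peak_hu)
      stopf("lumen_hu must satisfy 0 < lumen_hu < peak_hu")
    if (contrast_lumen$lumen_diameter_mm <= 0)
      stopf("lumen_diameter_mm must be positive")
    if (is.null(contrast_lumen$offset_mm))
      contrast_lumen$offset_mm <-
        (diameter_mm + contrast_lumen$lumen_diameter_mm) / 2
  }
  structure(
    list(shape_kind = shape_kind, diameter_mm = diameter_mm, peak_hu = peak_hu,
         psf_sigma_mm = psf_sigma_mm, noise_sd_hu = noise_sd_hu,
         fov_mm = fov_mm, matrix_size = as.integer(matrix_size),
         supersampling = as.integer(supersampling), hu_ceiling = hu_ceiling,
         hu_floor = hu_floor, wall_thickness_mm = wall_thickness_mm,
         contrast_lumen = contrast_lumen, seed = seed),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s D=%g mm, peak %g HU, sigma %g mm, noise %g HU,\n  FOV %g mm / %d px (spacing %.4g mm), supersampling %dx%s\n",
    x$shape_kind, x$diameter_mm, x$peak_hu, x$psf_sigma_mm, x$noise_sd_hu,
    x$fov_mm, x$matrix_size, x$fov_mm / x$matrix_size, x$supersampling,
    if (is.null(x$contrast_lumen)) "" else
      sprintf(", lumen %g HU D=%g mm", x$contrast_lumen$lumen_hu,
              x$contrast_lumen$lumen_diameter_mm)))
  invisible(x)
}

# amplitude field (HU, pre-blur) evaluated at physical coordinates;
# row_mm / col_mm are vectors of fine sample centres
amplitude_field <- function(spec, row_mm, col_mm) {
  cr <- spec$fov_mm / 2; cc <- spec$fov_mm / 2
  R <- spec$diameter_mm / 2
  d2 <- outer((row_mm - cr)^2, (col_mm - cc)^2, "+")
  mask <- switch(spec$shape_kind,
    concentric_disc = d2 <= R^2,
    eccentric_disc = (d2 <= R^2) &
      outer(rep(TRUE, length(row_mm)), (col_mm - cc) >= -R / 2, "&"),
    stent_like = d2 <= R^2 & d2 >= (R - spec$wall_thickness_mm)^2)
  amp <- spec$peak_hu * mask
  if (!is.null(spec$contrast_lumen)) {
    lu <- spec$contrast_lumen
    lr <- lu$lumen_diameter_mm / 2
    ld2 <- outer((row_mm - cr)^2, (col_mm - (cc + lu$offset_mm))^2, "+")
    amp <- amp + lu$lumen_hu * (ld2 <= lr^2)
  }
  amp
}

# noise-free, unclipped coarse-resolution field for a spec:
# rasterize supersampled -> Gaussian blur -> box-average. Only a patch around
# the shapes is rendered at fine resolution; the background is exactly 0 HU.
render_field <- function(spec) {
  n <- spec$matrix_size
  s <- spec$supersampling
  sp <- spec$fov_mm / n
  fine <- sp / s
  sigma <- spec$psf_sigma_mm

  if (sigma > 0) {
    taps <- 2L * as.integer(ceiling(5 * sigma / fine)) + 1L
    if (taps > n * s)
      stopf("PSF kernel (%d fine samples) larger than the image grid", taps)
  }

  # patch extent: shapes plus 5 sigma + 1 mm margin, snapped to coarse pixels
  cr <- spec$fov_mm / 2; cc <- spec$fov_mm / 2
  R <- spec$diameter_mm / 2
  margin <- 5 * sigma + 1
  r_lo <- cr - R - margin; r_hi <- cr + R + margin
  c_lo <- cc - R - margin
  c_hi_shape <- cc + R
  if (!is.null(spec$contrast_lumen))
    c_hi_shape <- max(c_hi_shape, cc + spec$contrast_lumen$offset_mm +
                        spec$contrast_lumen$lumen_diameter_mm / 2)
  c_hi <- c_hi_shape + margin
  i_lo <- max(1L, as.integer(floor(r_lo / sp)) + 1L)
  i_hi <- min(n, as.integer(ceiling(r_hi / sp)))
  j_lo <- max(1L, as.integer(floor(c_lo / sp)) + 1L)
  j_hi <- min(n, as.integer(ceiling(c_hi / sp)))

  # fine sample centres covering coarse pixels i_lo:i_hi, j_lo:j_hi
  fine_rows <- ((i_lo - 1L) * s + seq_len((i_hi - i_lo + 1L) * s) - 0.5) * fine
  fine_cols <- ((j_lo - 1L) * s + seq_len((j_hi - j_lo + 1L) * s) - 0.5) * fine
  patch <- amplitude_field(spec, fine_rows, fine_cols)

  if (sigma > 0) {
    h <- as.integer(ceiling(5 * sigma / fine))
    x <- (-h:h) * fine
    # cell-integrated Gaussian taps (exact mass over each fine sample cell):
    # second-order accurate against the discontinuous shape indicator
    k1 <- stats::pnorm((x + fine / 2) / sigma) - stats::pnorm((x - fine / 2) / sigma)
    k1 <- k1 / sum(k1)
    kern <- outer(k1, k1)
    # pad so the patch is at least as large as the kernel (zero background)
    pr <- max(0L, (2L * h + 1L) - nrow(patch))
    pc <- max(0L, (2L * h + 1L) - ncol(patch))
    if (pr > 0L || pc > 0L) {
      padded <- matrix(0, nrow(patch) + 2L * pr, ncol(patch) + 2L * pc)
      padded[pr + seq_len(nrow(patch)), pc + seq_len(ncol(patch))] <- patch
      blurred <- EBImage::filter2(padded, kern, boundary = 0)
      patch <- blurred[pr + seq_len(nrow(patch)), pc + seq_len(ncol(patch))]
    } else {
      patch <- EBImage::filter2(patch, kern, boundary = 0)
    }
  }

  coarse <- box_mean(patch, s)
  field <- matrix(0, n, n)
  field[i_lo:i_hi, j_lo:j_hi] <- coarse
  field
}

# mean over s x s blocks (partial-volume downsampling)
box_mean <- function(m, s) {
  if (s == 1L) return(m)
  nr <- nrow(m) %/% s; nc <- ncol(m) %/% s
  dim(m) <- c(s, nr, s * nc)
  m <- colMeans(m)                       # nr x (s*nc)
  dim(m) <- c(nr, s, nc)
  m <- aperm(m, c(2, 1, 3))              # s x nr x nc
  dim(m) <- c(s, nr * nc)
  m <- colMeans(m)
  dim(m) <- c(nr, nc)
  m
}

#' Render a synthetic calcification scene
#'
#' Pipeline: supersampled rasterization of the shape(s), scaling to `peak_hu`
#' (contrast lumen amplitudes add), isotropic Gaussian PSF blur, box-average
#' down to the reconstruction matrix, additive Gaussian noise, and clipping to
#' `[hu_floor, hu_ceiling]`. Deterministic for a fixed `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param energy_label optional label stored on the returned grid.
#' @param scan_id optional scan identifier stored on the returned grid.
#' @return an [image_grid()].
#' @export
render_scene <- function(spec, energy_label = NA_character_,
                         scan_id = NA_character_) {
  stopifnot(inherits(spec, "phantom_spec"))
  field <- render_field(spec)
  if (spec$noise_sd_hu > 0)
    field <- field + with_seed(spec$seed,
      matrix(stats::rnorm(length(field), 0, spec$noise_sd_hu), nrow(field)))
  field <- pmin(pmax(field, spec$hu_floor), spec$hu_ceiling)
  image_grid(field, spec$fov_mm / spec$matrix_size,
             energy_label = energy_label, scan_id = scan_id)
}

#' Render one scene at several X-ray energy levels
#'
#' All levels share geometry and PSF; only the peak amplitude (and consequent
#' clipping) differs — emulating virtual-monochromatic reconstructions of one
#' acquisition at different keV. The noise-free field is rendered once and
#' scaled per level (exact, by linearity of rasterization and blurring);
#' per-level noise streams are independent, seeded `seed + level_index - 1`.
#'
#' @param spec a [phantom_spec()]; its `peak_hu` anchors the scaling.
#' @param energy_table data frame with columns `energy_label`, `peak_hu`, and
#'   optionally `noise_sd_hu` (defaults to `spec$noise_sd_hu`).
#' @param seed base noise seed (default `spec$seed`).
#' @return list of [image_grid()]s, one per row of `energy_table`.
#' @seealso [default_energy_ladder()], [default_kvp_ladder()]
#' @export
render_energy_series <- function(spec, energy_table, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.data.frame(energy_table) || nrow(energy_table) == 0)
    stopf("`energy_table` is empty")
  if (!all(c("energy_label", "peak_hu") %in% names(energy_table)))
    stopf("`energy_table` needs columns energy_label and peak_hu")
  base_unit <- render_field(spec) / spec$peak_hu
  lapply(seq_len(nrow(energy_table)), function(l) {
    peak <- energy_table$peak_hu[l]
    nsd <- if ("noise_sd_hu" %in% names(energy_table))
      energy_table$noise_sd_hu[l] else spec$noise_sd_hu
    field <- base_unit * peak
    if (nsd > 0)
      field <- field + with_seed(if (is.null(seed)) NULL else seed + l - 1L,
        matrix(stats::rnorm(length(field), 0, nsd), nrow(field)))
    field <- pmin(pmax(field, spec$hu_floor), spec$hu_ceiling)
    image_grid(field, spec$fov_mm / spec$matrix_size,
               energy_label = as.character(energy_table$energy_label[l]))
  })
}

#' Continuum profile of a Gaussian-blurred disc (testing oracle)
#'
#' Exact continuous-domain value of a uniform disc of amplitude `peak_hu` and
#' radius `D/2` convolved with an isotropic Gaussian PSF, along a diameter.
#' The convolution of a disc indicator with a bivariate Gaussian equals the
#' probability that a noncentral chi-square variable (2 df, noncentrality
#' `(r/sigma)^2`) falls below `(R/sigma)^2`, so the value is computed in
#' closed form via [stats::pchisq()]. Defined only for noise-free concentric
#' discs; values are clipped at `hu_ceiling`.
#'
#' @param spec a noise-free concentric-disc [phantom_spec()].
#' @param position_mm signed distance from the disc centre, mm (vectorized).
#' @return attenuation value(s), HU.
#' @export
analytic_profile <- function(spec, position_mm) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$shape_kind != "concentric_disc" || spec$noise_sd_hu > 0 ||
      !is.null(spec$contrast_lumen))
    stopf("analytic_profile is defined only for noise-free concentric discs")
  R <- spec$diameter_mm / 2
  r <- abs(position_mm)
  s <- spec$psf_sigma_mm
  if (s == 0) {
    v <- spec$peak_hu * ((r < R) + 0.5 * (r == R))
  } else {
    v <- spec$peak_hu * stats::pchisq((R / s)^2, df = 2, ncp = (r / s)^2)
  }
  pmin(v, spec$hu_ceiling)
}

#' Default virtual-monochromatic energy ladder
#'
#' Five keV levels (40–140) with peak calcification attenuation and background
#' noise SD typical of a dual-source scanner's virtual monochromatic phantom
#' reconstructions; the 40 keV peak sits at the 12-bit display ceiling
#' (3071 HU). Used as the generator's default study conditions.
#'
#' @return data frame with columns `energy_label`, `peak_hu`, `noise_sd_hu`.
#' @export
default_energy_ladder <- function() {
  data.frame(
    energy_label = c("40keV", "70keV", "100keV", "130keV", "140keV"),
    peak_hu = c(3071, 1404, 871, 687, 654),
    noise_sd_hu = c(15.41, 7.33, 7.73, 8.14, 8.23))
}

#' Default polychromatic (kVp) energy ladder
#'
#' Four tube-voltage levels (80–140 kVp) with monotonically decreasing peak
#' calcification attenuation, typical of conventional polychromatic phantom
#' scans on a dual-source scanner.
#'
#' @return data frame with columns `energy_label`, `peak_hu`, `noise_sd_hu`.
#' @export
default_kvp_ladder <- function() {
  data.frame(
    energy_label = c("80kVp", "100kVp", "120kVp", "140kVp"),
    peak_hu = c(2276, 1873, 1645, 1505),
    noise_sd_hu = c(12.10, 10.94, 10.41, 9.17))
}
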