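# Independent oracles used across test files.

# Continuum value of disc (x) Gaussian by brute-force quadrature: midpoint rule
# over the chord direction with the transverse integral via the normal CDF.
# Independent of the noncentral-chi-square route in analytic_profile().
brute_blurred_disc <- function(peak_hu, diameter_mm, sigma_mm, r_mm,
                               step_mm = 0.001) {
  R <- diameter_mm / 2
  x <- seq(-R + step_mm / 2, R - step_mm / 2, by = step_mm)
  half <- sqrt(pmax(0, R^2 - x^2))
  dens <- stats::dnorm(x, mean = r_mm, sd = sigma_mm)
  trans <- stats::pnorm(half / sigma_mm) - stats::pnorm(-half / sigma_mm)
  peak_hu * sum(dens * trans) * step_mm
}

# Dense root-finding on the continuum blurred-disc profile: full width at a
# fractional threshold of the centre value.
cont_width <- function(spec, fraction) {
  f <- function(r) analytic_profile(spec, r)
  pk <- f(0)
  2 * stats::uniroot(function(r) f(r) - fraction * pk,
                     c(0, spec$fov_mm / 2), tol = 1e-12)$root
}

# Continuum halo per direction: distance between the 1/3-peak and the
# min_fraction-peak crossings.
cont_halo <- function(spec, min_fraction = 0.05, actual_fraction = 1 / 3) {
  (cont_width(spec, min_fraction) - cont_width(spec, actual_fraction)) / 2
}

# Box-averaged continuum oracle for the central pixel row: the exact mean of
# the blurred-disc field over each pixel's area, by dense midpoint quadrature.
box_avg_center_row <- function(spec, nq = 32) {
  n <- spec$matrix_size
  sp <- spec$fov_mm / n
  ctr <- spec$fov_mm / 2
  i0 <- ceiling(ctr / sp)
  u <- ((seq_len(nq)) - 0.5) / nq
  rows <- (i0 - 1) * sp + u * sp
  vapply(seq_len(n), function(j) {
    cols <- (j - 1) * sp + u * sp
    r <- sqrt(outer((rows - ctr)^2, (cols - ctr)^2, "+"))
    mean(analytic_profile(spec, r))
  }, numeric(1))
}
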