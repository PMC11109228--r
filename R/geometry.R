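# Phantom distortion-angle arithmetic: a printed phantom imaged slightly
# off-axis foreshortens in-plane lengths; two orthogonal view angles combine
# into one axial distortion angle, whose cosine gives the length error.

#' Combine two orthogonal distortion angles into the axial distortion angle
#'
#' `theta = (180/pi) * arctan( sqrt( tan(theta1)^2 + tan(theta2)^2 ) )`,
#' where the inputs are the distortion angles observed in the anterior and
#' left views of the reconstructed phantom.
#'
#' @param theta1_deg,theta2_deg view angles in degrees, each in `[0, 90)`.
#'   Vectorized (recycled to common length).
#' @return combined axial distortion angle, degrees.
#' @export
combine_distortion <- function(theta1_deg, theta2_deg) {
  if (any(theta1_deg < 0 | theta1_deg >= 90) ||
      any(theta2_deg < 0 | theta2_deg >= 90))
    stopf("angles must lie in [0, 90) degrees")
  t1 <- tan(theta1_deg * pi / 180)
  t2 <- tan(theta2_deg * pi / 180)
  atan(sqrt(t1^2 + t2^2)) * 180 / pi
}

#' Length-measurement error implied by an axial distortion angle
#'
#' A length measured in a plane tilted by `theta` is foreshortened by the
#' factor `cos(theta)`; the relative error `(1 - 1/cos(theta)) * 100` is
#' reported as a magnitude (percent).
#'
#' @param theta_deg distortion angle(s), degrees, in `[0, 90)`.
#' @return absolute percent measurement error.
#' @export
measurement_error <- function(theta_deg) {
  if (any(theta_deg < 0 | theta_deg >= 90))
    stopf("`theta_deg` must lie in [0, 90) degrees")
  abs(1 - 1 / cos(theta_deg * pi / 180)) * 100
}

#' Summarize a set of distortion angles and their implied errors
#'
#' @param angles_deg non-empty numeric vector of distortion angles, degrees.
#' @param error_digits decimal places the per-scan percent errors are rounded
#'   to before summarizing (default 2, the precision such errors are tabulated
#'   at; use `NULL` for full precision).
#' @return list with `angle` and `error_pct` components, each holding `mean`,
#'   `sd` (sample, n-1 denominator; 0 with `sd_undefined = TRUE` for a single
#'   angle) and `max`, plus `n`.
#' @export
summarize_angles <- function(angles_deg, error_digits = 2) {
  if (length(angles_deg) == 0) stopf("empty angle list")
  err <- measurement_error(angles_deg)
  if (!is.null(error_digits)) err <- round(err, error_digits)
  one <- length(angles_deg) == 1L
  list(
    angle = list(mean = mean(angles_deg),
                 sd = if (one) 0 else stats::sd(angles_deg),
                 max = max(angles_deg)),
    error_pct = list(mean = mean(err),
                     sd = if (one) 0 else stats::sd(err),
                     max = max(err)),
    n = length(angles_deg), sd_undefined = one)
}

#' Distortion angles from repeat phantom scans on three CT scanners
#'
#' Axial distortion angles (degrees) of a 3D-printed calcification phantom,
#' from five repeat scans on each of three dual-energy CT scanners, bundled
#' as the package's reference input for the distortion-error arithmetic.
#'
#' @return data frame with columns `scanner`, `scan`, `angle_deg`.
#' @export
phantom_distortion_angles <- function() {
  path <- system.file("extdata", "phantom_distortion_angles.csv",
                      package = "bloomquant", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
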