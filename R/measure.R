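# Line-profile measurement of the actual calcified length (FW3M) and the
# surrounding brightened halo ("adjacent pixels affected by calcification").

# Locate the calcification: threshold at 1/3 of the (windowed) maximum,
# label connected components, pick the region nearest the hint (or the
# largest), and return its intensity-weighted centroid plus the region peak.
locate_calcification <- function(image, hint = NULL, window_mm = 40) {
  px <- image$pixels
  sp <- image$pixel_spacing_mm
  nr <- nrow(px); nc <- ncol(px)
  if (!is.null(hint)) {
    hi <- max(1L, min(nr, as.integer(round(hint[1] / sp[1] + 0.5))))
    hj <- max(1L, min(nc, as.integer(round(hint[2] / sp[2] + 0.5))))
    wr <- as.integer(ceiling(window_mm / 2 / sp[1]))
    wc <- as.integer(ceiling(window_mm / 2 / sp[2]))
    ri <- max(1L, hi - wr):min(nr, hi + wr)
    ci <- max(1L, hj - wc):min(nc, hj + wc)
  } else {
    ri <- seq_len(nr); ci <- seq_len(nc)
  }
  sub <- px[ri, ci, drop = FALSE]
  mx <- max(sub)
  if (mx <= 0) stopf("no calcification found: no pixel above threshold")
  thr <- mx / 3
  mask <- sub > thr
  if (!any(mask)) stopf("no calcification found: no pixel above threshold")
  lab <- EBImage::bwlabel(mask)
  if (!is.null(hint)) {
    # region nearest the hint: smallest centre-of-mass distance
    ids <- seq_len(max(lab))
    hrow <- hint[1] / sp[1] + 0.5 - (ri[1] - 1L)
    hcol <- hint[2] / sp[2] + 0.5 - (ci[1] - 1L)
    dists <- vapply(ids, function(id) {
      w <- which(lab == id, arr.ind = TRUE)
      sqrt((mean(w[, 1]) - hrow)^2 + (mean(w[, 2]) - hcol)^2)
    }, numeric(1))
    pick <- ids[which.min(dists)]
  } else {
    pick <- which.max(tabulate(lab[lab > 0]))
  }
  w <- which(lab == pick, arr.ind = TRUE)
  vals <- sub[lab == pick]
  # intensity-weighted centroid in physical mm (full-grid frame)
  rows_mm <- (w[, 1] + (ri[1] - 1L) - 0.5) * sp[1]
  cols_mm <- (w[, 2] + (ci[1] - 1L) - 0.5) * sp[2]
  list(center_mm = c(sum(rows_mm * vals), sum(cols_mm * vals)) / sum(vals),
       peak_hu = max(vals),
       region_idx = cbind(w[, 1] + (ri[1] - 1L), w[, 2] + (ci[1] - 1L)))
}

#' Find the centre of a calcification
#'
#' Thresholds the image at one third of its maximum (restricted to a window
#' around `hint` when given), labels connected above-threshold regions, and
#' returns the intensity-weighted centroid of the region nearest the hint
#' (largest region when no hint is given).
#'
#' @param image an [image_grid()].
#' @param hint optional approximate centre, `c(row_mm, col_mm)`.
#' @param window_mm side length of the search window around `hint`, mm.
#' @return centre position `c(row_mm, col_mm)`.
#' @export
find_center <- function(image, hint = NULL, window_mm = 40) {
  stopifnot(inherits(image, "image_grid"))
  locate_calcification(image, hint, window_mm)$center_mm
}

#' Extract a line profile along a cardinal direction
#'
#' Profiles follow the pixel lattice: the row/column through the pixel nearest
#' `center` is sampled without interpolation. Directional profiles run from the
#' centre pixel outward to the grid edge with positions measured as distance
#' from the centre pixel; full profiles run edge to edge in absolute grid mm.
#'
#' @param image an [image_grid()].
#' @param center `c(row_mm, col_mm)` inside the grid.
#' @param direction one of `"up"`, `"down"`, `"left"`, `"right"`,
#'   `"full_horizontal"`, `"full_vertical"`.
#' @return an object of class `line_profile` with fields `positions_mm`,
#'   `values_hu`, `direction`, `center_position_mm`, `spacing_mm`.
#' @export
extract_profile <- function(image, center,
                            direction = c("full_horizontal", "full_vertical",
                                          "up", "down", "left", "right")) {
  stopifnot(inherits(image, "image_grid"))
  direction <- match.arg(direction)
  px <- image$pixels
  sp <- image$pixel_spacing_mm
  nr <- nrow(px); nc <- ncol(px)
  if (center[1] < 0 || center[1] > nr * sp[1] ||
      center[2] < 0 || center[2] > nc * sp[2])
    stopf("center lies outside the grid")
  i0 <- max(1L, min(nr, as.integer(ceiling(center[1] / sp[1]))))
  j0 <- max(1L, min(nc, as.integer(ceiling(center[2] / sp[2]))))
  ctr_mm <- c((i0 - 0.5) * sp[1], (j0 - 0.5) * sp[2])
  prof <- switch(direction,
    full_horizontal = list(pos = (seq_len(nc) - 0.5) * sp[2],
                           val = px[i0, ], center = ctr_mm[2], spacing = sp[2]),
    full_vertical = list(pos = (seq_len(nr) - 0.5) * sp[1],
                         val = px[, j0], center = ctr_mm[1], spacing = sp[1]),
    right = list(pos = ((j0:nc) - j0) * sp[2], val = px[i0, j0:nc],
                 center = 0, spacing = sp[2]),
    left = list(pos = (j0 - (j0:1)) * sp[2], val = px[i0, j0:1],
                center = 0, spacing = sp[2]),
    down = list(pos = ((i0:nr) - i0) * sp[1], val = px[i0:nr, j0],
                center = 0, spacing = sp[1]),
    up = list(pos = (i0 - (i0:1)) * sp[1], val = px[i0:1, j0],
              center = 0, spacing = sp[1]))
  structure(
    list(positions_mm = prof$pos, values_hu = unname(prof$val),
         direction = direction, center_position_mm = prof$center,
         spacing_mm = prof$spacing),
    class = "line_profile")
}

#' Construct a line profile directly from vectors
#'
#' @param positions_mm strictly increasing physical positions, mm.
#' @param values_hu attenuation values, HU.
#' @param direction direction label.
#' @param center_position_mm reference position, mm.
#' @return a `line_profile`.
#' @export
line_profile <- function(positions_mm, values_hu, direction = "full_horizontal",
                         center_position_mm = NULL) {
  if (length(positions_mm) != length(values_hu) || length(positions_mm) < 3)
    stopf("positions and values must have equal length >= 3")
  d <- diff(positions_mm)
  if (any(d <= 0)) stopf("positions must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * mean(d))
    stopf("positions must be uniformly spaced")
  structure(
    list(positions_mm = positions_mm, values_hu = values_hu,
         direction = direction,
         center_position_mm = center_position_mm %||%
           positions_mm[which.max(values_hu)],
         spacing_mm = mean(d)),
    class = "line_profile")
}

# Search outward from index `from` in steps of `step` (+1 or -1) for the
# first adjacent pair bracketing threshold T; linear interpolation places the
# crossing. A sample exactly equal to T is itself the crossing.
outward_crossing <- function(pos, val, from, step, T) {
  i <- from
  n <- length(val)
  while (i >= 1L && i <= n) {
    if (val[i] == T) return(pos[i])
    j <- i + step
    if (j < 1L || j > n) return(NA_real_)
    if (val[i] > T && val[j] < T)
      return(pos[i] + (T - val[i]) / (val[j] - val[i]) * (pos[j] - pos[i]))
    i <- j
  }
  NA_real_
}

#' Full width of a profile at a fractional threshold
#'
#' Threshold `T = background + fraction * (peak - background)`; starting at the
#' peak sample and moving outward on each side, the first adjacent sample pair
#' bracketing `T` defines the crossing, placed by linear interpolation
#' (sub-pixel). `fraction = 1/2` gives the FWHM, `1/3` the FW3M used as the
#' actual calcified length.
#'
#' @param profile a full (edge-to-edge) `line_profile`.
#' @param fraction relative threshold in (0, 1).
#' @param background background attenuation, HU (0 per convention).
#' @param peak_hu optional peak reference overriding the profile maximum
#'   (e.g. the maximum of the calcification's connected region).
#' @return object of class `width_estimate`: `fraction`, `width_mm`,
#'   `left_crossing_mm`, `right_crossing_mm`, `peak_hu`, `threshold_hu`.
#' @export
width_at_fraction <- function(profile, fraction, background = 0,
                              peak_hu = NULL) {
  stopifnot(inherits(profile, "line_profile"))
  if (!is_scalar_num(fraction) || fraction <= 0 || fraction >= 1)
    stopf("`fraction` must lie in (0, 1)")
  val <- profile$values_hu
  pos <- profile$positions_mm
  pk <- peak_hu %||% max(val)
  if (pk <= background) stopf("no peak: profile maximum not above background")
  T <- background + fraction * (pk - background)
  ipk <- which.max(val)
  if (val[ipk] < T)
    stopf("profile maximum lies below the threshold")
  left <- outward_crossing(pos, val, ipk, -1L, T)
  right <- outward_crossing(pos, val, ipk, +1L, T)
  if (is.na(left) || is.na(right)) {
    side <- c("left", "right")[c(is.na(left), is.na(right))]
    stopf("unbounded width: no %s-side crossing below the threshold",
          paste(side, collapse = " and "))
  }
  structure(
    list(fraction = fraction, width_mm = right - left,
         left_crossing_mm = left, right_crossing_mm = right,
         peak_hu = pk, threshold_hu = T),
    class = "width_estimate")
}

#' Brightened halo length beyond the FW3M edge in one direction
#'
#' Starting at the FW3M crossing and moving outward, finds the sub-pixel
#' crossing of the minimum threshold (`min_fraction * peak_hu`, default 5% of
#' peak). The halo is the distance between the two crossings, clamped at 0.
#' A direction is flagged (halo reported as 0) when the profile, while still
#' above the minimum threshold, re-rises from its running minimum by more than
#' `rise_tol_frac * peak_hu`, dwells in a `plateau_tol_frac * peak_hu` band for
#' at least `plateau_len_mm` (a contrast-agent plateau), or never crosses the
#' threshold before the grid edge.
#'
#' @param profile a directional `line_profile` (positions = distance from the
#'   calcification centre, increasing outward).
#' @param peak_hu peak attenuation of the calcification, HU.
#' @param fw3m_crossing_mm position of the FW3M edge on this profile, mm.
#' @param min_fraction lower threshold as a fraction of peak (default 0.05).
#' @param rise_tol_frac re-rise flag tolerance, fraction of peak.
#' @param plateau_len_mm,plateau_tol_frac sustained-plateau flag parameters.
#' @return list with `halo_mm`, `flagged`, `flag_reason`
#'   (`""`, `"rerise"`, `"plateau"`, or `"no_crossing"`).
#' @export
brightened_extent <- function(profile, peak_hu, fw3m_crossing_mm,
                              min_fraction = 0.05, rise_tol_frac = 0.10,
                              plateau_len_mm = 1, plateau_tol_frac = 0.05) {
  stopifnot(inherits(profile, "line_profile"))
  pos <- profile$positions_mm
  val <- profile$values_hu
  n <- length(pos)
  if (peak_hu <= 0) stopf("`peak_hu` must be positive")
  if (fw3m_crossing_mm < pos[1] || fw3m_crossing_mm > pos[n])
    stopf("fw3m_crossing_mm does not lie on this profile")
  T <- min_fraction * peak_hu
  out <- function(halo, reason = "")
    list(halo_mm = max(0, halo), flagged = nzchar(reason), flag_reason = reason)

  k0 <- findInterval(fw3m_crossing_mm, pos)         # pos[k0] <= crossing
  # value at the start point by interpolation
  v_start <- if (pos[k0] == fw3m_crossing_mm || k0 == n) val[k0] else
    val[k0] + (fw3m_crossing_mm - pos[k0]) / (pos[k0 + 1] - pos[k0]) *
      (val[k0 + 1] - val[k0])
  if (v_start < T) return(out(0))                   # already below 5% of peak

  run_min <- v_start
  anchor_pos <- fw3m_crossing_mm
  anchor_val <- v_start
  prev_pos <- fw3m_crossing_mm
  prev_val <- v_start
  k <- k0 + 1L
  while (k <= n) {
    v <- val[k]
    if (v < T) {
      x <- prev_pos + (T - prev_val) / (v - prev_val) * (pos[k] - prev_pos)
      return(out(x - fw3m_crossing_mm))
    }
    if (v == T) return(out(pos[k] - fw3m_crossing_mm))
    if (v > run_min + rise_tol_frac * peak_hu) return(out(0, "rerise"))
    run_min <- min(run_min, v)
    # sustained plateau: values within a narrow band for >= plateau_len_mm
    if (abs(v - anchor_val) > plateau_tol_frac * peak_hu) {
      anchor_pos <- pos[k]; anchor_val <- v
    } else if (pos[k] - anchor_pos >= plateau_len_mm) {
      return(out(0, "plateau"))
    }
    prev_pos <- pos[k]; prev_val <- v
    k <- k + 1L
  }
  out(0, "no_crossing")
}

#' Measure blooming of a calcification
#'
#' Computes the actual calcified length (FW3M along the horizontal and
#' vertical axes through the centre, averaged), the per-direction brightened
#' halos (FW3M edge to 5%-of-peak crossing in the up/down/left/right
#' directions), and the adjacent-pixels-affected metric: the mean of the four
#' per-direction halos, in millimetres and in pixel-spacing units. Flagged
#' directions (contrast plateau / no crossing) contribute 0. The peak
#' reference for all thresholds is the maximum within the calcification's
#' connected region, so brighter structures elsewhere cannot corrupt them.
#'
#' @param image an [image_grid()].
#' @param center optional hint `c(row_mm, col_mm)`; the centre used is always
#'   the detected intensity-weighted centroid.
#' @param actual_fraction threshold fraction for the actual length (1/3).
#' @param min_fraction lower brightened threshold, fraction of peak (0.05).
#' @param ... further arguments passed to [brightened_extent()].
#' @return object of class `bloom_measurement`.
#' @export
measure_bloom <- function(image, center = NULL, actual_fraction = 1 / 3,
                          min_fraction = 0.05, ...) {
  stopifnot(inherits(image, "image_grid"))
  loc <- locate_calcification(image, hint = center)
  ctr <- loc$center_mm
  pk <- loc$peak_hu

  ph <- extract_profile(image, ctr, "full_horizontal")
  pv <- extract_profile(image, ctr, "full_vertical")
  wh <- width_at_fraction(ph, actual_fraction, peak_hu = pk)
  wv <- width_at_fraction(pv, actual_fraction, peak_hu = pk)
  length_actual <- (wh$width_mm + wv$width_mm) / 2

  # directional profiles; FW3M crossings converted to distance-from-centre
  dirs <- list(
    up    = list(prof = extract_profile(image, ctr, "up"),
                 start = pv$center_position_mm - wv$left_crossing_mm),
    down  = list(prof = extract_profile(image, ctr, "down"),
                 start = wv$right_crossing_mm - pv$center_position_mm),
    left  = list(prof = extract_profile(image, ctr, "left"),
                 start = ph$center_position_mm - wh$left_crossing_mm),
    right = list(prof = extract_profile(image, ctr, "right"),
                 start = wh$right_crossing_mm - ph$center_position_mm))
  ext <- lapply(dirs, function(d)
    brightened_extent(d$prof, pk, max(0, d$start),
                      min_fraction = min_fraction, ...))
  halo <- vapply(ext, `[[`, numeric(1), "halo_mm")
  flags <- vapply(ext, `[[`, character(1), "flag_reason")
  spacing <- vapply(dirs, function(d) d$prof$spacing_mm, numeric(1))

  adjacent_mm <- mean(halo)
  structure(
    list(length_actual_mm = length_actual,
         length_actual_h_mm = wh$width_mm,
         length_actual_v_mm = wv$width_mm,
         length_brightened_mm = length_actual + adjacent_mm,
         adjacent_affected_mm = adjacent_mm,
         adjacent_affected_px = mean(halo / spacing),
         per_direction_halo_mm = halo,
         flags = flags,
         center_mm = ctr, peak_hu = pk),
    class = "bloom_measurement")
}

#' @export
print.bloom_measurement <- function(x, ...) {
  cat(sprintf(
    paste0("<bloom_measurement>\n  actual length (FW3M): %.3f mm (h %.3f, v %.3f)\n",
           "  brightened length:    %.3f mm\n",
           "  adjacent affected:    %.3f mm (%.3f px)\n",
           "  halos u/d/l/r (mm):   %.3f / %.3f / %.3f / %.3f\n"),
    x$length_actual_mm, x$length_actual_h_mm, x$length_actual_v_mm,
    x$length_brightened_mm, x$adjacent_affected_mm, x$adjacent_affected_px,
    x$per_direction_halo_mm["up"], x$per_direction_halo_mm["down"],
    x$per_direction_halo_mm["left"], x$per_direction_halo_mm["right"]))
  fl <- x$flags[nzchar(x$flags)]
  if (length(fl))
    cat("  flagged:", paste(names(fl), fl, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Compare FW3M and FWHM diameter-estimation error over a set of scenes
#'
#' Renders noise-controlled blurred-disc scenes for each diameter x energy
#' combination, measures the width at both fractions (1/3 and 1/2), and
#' summarizes the absolute error against the known true diameter.
#'
#' @param diameters_mm vector of true calcification diameters, mm.
#' @param peak_hus vector of per-energy peak amplitudes, HU.
#' @param psf_sigma_mm Gaussian PSF SD, mm.
#' @param fov_mm,matrix_size,noise_sd_hu,supersampling scene parameters.
#' @param seed base noise seed (incremented per scene).
#' @return data frame with columns `method`, `mean_error_mm`, `sem_mm`, `n`;
#'   per-case errors attached as attribute `"errors"`.
#' @export
fw3m_vs_fwhm_error <- function(diameters_mm = c(4, 5, 6),
                               peak_hus = default_energy_ladder()$peak_hu,
                               psf_sigma_mm = 0.5, fov_mm = 300,
                               matrix_size = 512, noise_sd_hu = 0,
                               supersampling = 16L, seed = NULL) {
  cases <- expand.grid(D = diameters_mm, peak = peak_hus)
  err <- lapply(seq_len(nrow(cases)), function(i) {
    spec <- phantom_spec("concentric_disc", cases$D[i], cases$peak[i],
                         psf_sigma_mm = psf_sigma_mm, noise_sd_hu = noise_sd_hu,
                         fov_mm = fov_mm, matrix_size = matrix_size,
                         supersampling = supersampling,
                         seed = if (is.null(seed)) NULL else seed + i)
    img <- render_scene(spec)
    loc <- locate_calcification(img)
    ph <- extract_profile(img, loc$center_mm, "full_horizontal")
    pv <- extract_profile(img, loc$center_mm, "full_vertical")
    w <- function(f) (width_at_fraction(ph, f, peak_hu = loc$peak_hu)$width_mm +
                      width_at_fraction(pv, f, peak_hu = loc$peak_hu)$width_mm) / 2
    c(fw3m = abs(w(1 / 3) - cases$D[i]), fwhm = abs(w(1 / 2) - cases$D[i]))
  })
  err <- do.call(rbind, err)
  res <- data.frame(
    method = c("FW3M", "FWHM"),
    mean_error_mm = c(mean(err[, "fw3m"]), mean(err[, "fwhm"])),
    sem_mm = c(stats::sd(err[, "fw3m"]), stats::sd(err[, "fwhm"])) /
      sqrt(nrow(err)),
    n = nrow(err))
  attr(res, "errors") <- err
  res
}
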