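# Image-quality QC: contrast-to-noise ratio, signal-to-noise ratio and noise
# from a region of interest (the calcification) and a background region.

#' ROI image-quality statistics
#'
#' `CNR = (mean ROI - mean background) / SD background`,
#' `SNR = mean ROI / SD background`, `noise = SD background` (sample SD,
#' n-1 denominator), plus the maximum HU within the ROI.
#'
#' @param image an [image_grid()].
#' @param roi_mask,bg_mask logical matrices of the image's dimensions; must be
#'   non-empty and disjoint. `bg_mask` needs at least 2 pixels.
#' @return object of class `roi_stats` with fields `mean_hu_roi`,
#'   `mean_hu_bg`, `sd_hu_bg`, `cnr`, `snr`, `noise`, `max_hu`,
#'   `n_roi`, `n_bg`.
#' @export
region_stats <- function(image, roi_mask, bg_mask) {
  stopifnot(inherits(image, "image_grid"))
  px <- image$pixels
  for (nm in c("roi_mask", "bg_mask")) {
    m <- get(nm)
    if (!is.logical(m) || !identical(dim(m), dim(px)))
      stopf("`%s` must be a logical matrix matching the image dimensions", nm)
    if (!any(m)) stopf("`%s` is empty", nm)
  }
  if (any(roi_mask & bg_mask)) stopf("ROI and background masks overlap")
  if (sum(bg_mask) < 2) stopf("background mask needs at least 2 pixels")
  roi <- px[roi_mask]; bg <- px[bg_mask]
  sd_bg <- stats::sd(bg)
  if (sd_bg == 0) stopf("zero background SD: CNR/SNR undefined")
  structure(
    list(mean_hu_roi = mean(roi), mean_hu_bg = mean(bg), sd_hu_bg = sd_bg,
         cnr = (mean(roi) - mean(bg)) / sd_bg,
         snr = mean(roi) / sd_bg, noise = sd_bg, max_hu = max(roi),
         n_roi = sum(roi_mask), n_bg = sum(bg_mask)),
    class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf(
    "<roi_stats> CNR %.2f, SNR %.2f, noise %.2f HU, max %.0f HU (ROI n=%d, bg n=%d)\n",
    x$cnr, x$snr, x$noise, x$max_hu, x$n_roi, x$n_bg))
  invisible(x)
}

#' Default ROI / background regions for a synthetic scene
#'
#' ROI: pixels of the calcification's connected region above one third of its
#' peak. Background: a rectangle placed below the ROI bounding box (phantom
#' mode) or to its right (clinical mode, avoiding the contrast lumen which sits
#' to the right — the rectangle is offset further out).
#'
#' @param image an [image_grid()].
#' @param mode `"phantom"` (background below the ROI) or `"clinical"`
#'   (background to the right).
#' @param bg_size_px side length of the square background region, pixels.
#' @param gap_mm gap between the ROI bounding box and the background region.
#' @return list with logical matrices `roi_mask` and `bg_mask`.
#' @export
default_regions <- function(image, mode = c("phantom", "clinical"),
                            bg_size_px = 32L, gap_mm = 5) {
  mode <- match.arg(mode)
  loc <- locate_calcification(image)
  px <- image$pixels
  sp <- image$pixel_spacing_mm
  roi_mask <- matrix(FALSE, nrow(px), ncol(px))
  roi_mask[loc$region_idx] <- TRUE
  bb <- c(range(loc$region_idx[, 1]), range(loc$region_idx[, 2]))
  bg_mask <- matrix(FALSE, nrow(px), ncol(px))
  if (mode == "phantom") {
    r0 <- bb[2] + as.integer(ceiling(gap_mm / sp[1]))
    rows <- r0:min(nrow(px), r0 + bg_size_px - 1L)
    c0 <- max(1L, as.integer(round((bb[3] + bb[4]) / 2 - bg_size_px / 2)))
    cols <- c0:min(ncol(px), c0 + bg_size_px - 1L)
  } else {
    c0 <- bb[4] + as.integer(ceiling(gap_mm / sp[2]))
    cols <- c0:min(ncol(px), c0 + bg_size_px - 1L)
    r0 <- max(1L, as.integer(round((bb[1] + bb[2]) / 2 - bg_size_px / 2)))
    rows <- r0:min(nrow(px), r0 + bg_size_px - 1L)
  }
  if (max(rows) > nrow(px) || max(cols) > ncol(px) ||
      length(rows) < 2 || length(cols) < 2)
    stopf("no room for the background region; shrink bg_size_px or gap_mm")
  bg_mask[rows, cols] <- TRUE
  bg_mask[roi_mask] <- FALSE
  list(roi_mask = roi_mask, bg_mask = bg_mask)
}
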