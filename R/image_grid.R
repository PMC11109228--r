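#' CT-like image grid in Hounsfield units
#'
#' The basic container all measurement operates on: a rectangular matrix of
#' attenuation values (HU) plus the physical pixel spacing. Row index runs
#' top-to-bottom, column index left-to-right; the centre of pixel `(i, j)`
#' sits at `((i - 0.5) * spacing_row, (j - 0.5) * spacing_col)` millimetres
#' from the top-left corner of the grid.
#'
#' @param pixels numeric matrix of attenuation values in HU.
#' @param pixel_spacing_mm numeric of length 1 or 2, (row, col) spacing in mm.
#' @param energy_label optional label of the X-ray energy level (e.g. "70keV").
#' @param scan_id optional scan identifier.
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(pixels, pixel_spacing_mm, energy_label = NA_character_,
                       scan_id = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(dim(pixels) < 1L))
    stopf("`pixels` must be a non-empty numeric matrix")
  if (anyNA(pixels)) stopf("`pixels` contains NA")
  sp <- as.numeric(pixel_spacing_mm)
  if (length(sp) == 1L) sp <- c(sp, sp)
  if (length(sp) != 2L || any(!is.finite(sp)) || any(sp <= 0))
    stopf("`pixel_spacing_mm` must be 1 or 2 strictly positive values")
  structure(
    list(pixels = pixels, pixel_spacing_mm = sp,
         energy_label = as.character(energy_label),
         scan_id = as.character(scan_id)),
    class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d px, spacing %.4g x %.4g mm",
              nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2]))
  if (!is.na(x$energy_label)) cat(", energy", x$energy_label)
  cat(sprintf(", HU range [%.4g, %.4g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$pixels)

# physical coordinates (mm) of pixel centres
grid_row_mm <- function(image) (seq_len(nrow(image$pixels)) - 0.5) * image$pixel_spacing_mm[1]
grid_col_mm <- function(image) (seq_len(ncol(image$pixels)) - 0.5) * image$pixel_spacing_mm[2]
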