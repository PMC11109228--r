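# Delimited-text image I/O with a key-value metadata sidecar.

sidecar_path <- function(path) paste0(path, ".meta")

#' Write an image grid as a delimited-text matrix with a metadata sidecar
#'
#' One text row per image row, tab-separated. A sidecar file (`<path>.meta`)
#' records `key = value` lines: pixel spacing, energy label, scan id. Values
#' are written at full precision by default so that re-reading reproduces
#' measurements exactly; pass `digits = 0` for integer HU output.
#'
#' @param image an [image_grid()].
#' @param path output file path.
#' @param digits `NULL` for full precision (`%.17g`), or an integer number of
#'   decimal places.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, digits = NULL) {
  stopifnot(inherits(image, "image_grid"))
  px <- image$pixels
  fmt <- if (is.null(digits)) "%.17g" else paste0("%.", digits, "f")
  lines <- apply(px, 1, function(row) paste(sprintf(fmt, row), collapse = "\t"))
  writeLines(lines, path)
  meta <- c(
    sprintf("pixel_spacing_row_mm = %.17g", image$pixel_spacing_mm[1]),
    sprintf("pixel_spacing_col_mm = %.17g", image$pixel_spacing_mm[2]),
    sprintf("energy_label = %s", image$energy_label),
    sprintf("scan_id = %s", image$scan_id))
  writeLines(meta, sidecar_path(path))
  invisible(path)
}

#' Read an image grid from a delimited-text matrix
#'
#' Accepts tab- or comma-separated matrices without a header. Pixel spacing is
#' taken from the `<path>.meta` sidecar (`key = value` lines) or from the
#' `pixel_spacing_mm` argument, which takes precedence when supplied.
#'
#' @param path input file path.
#' @param pixel_spacing_mm optional spacing override, length 1 or 2, mm.
#' @return an [image_grid()].
#' @export
read_image <- function(path, pixel_spacing_mm = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  meta <- list()
  if (file.exists(sidecar_path(path))) {
    for (ln in readLines(sidecar_path(path))) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2)
        meta[[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  if (is.null(pixel_spacing_mm)) {
    if (is.null(meta$pixel_spacing_row_mm))
      stopf("no pixel spacing: missing sidecar %s and no `pixel_spacing_mm`",
            sidecar_path(path))
    pixel_spacing_mm <- c(as.numeric(meta$pixel_spacing_row_mm),
                          as.numeric(meta$pixel_spacing_col_mm %||%
                                       meta$pixel_spacing_row_mm))
  }
  image_grid(m, pixel_spacing_mm,
             energy_label = meta$energy_label %||% NA_character_,
             scan_id = meta$scan_id %||% NA_character_)
}
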