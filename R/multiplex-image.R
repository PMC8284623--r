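#' Multiplex immunofluorescence image
#'
#' Container for a multi-channel 2-D fluorescence image: one intensity raster
#' per marker, a physical pixel size, and case-level metadata. All rasters
#' must share one shape; the panel must contain the pan-myeloid marker
#' \code{Iba1} plus exactly one microglial-specific marker (\code{P2RY12} or
#' \code{TMEM119}), and optionally one TAM-enriched marker (\code{CD14} or
#' \code{CD163}).
#'
#' @param channels named list of numeric matrices, one per marker. Matrices
#'   are indexed \code{[row, col]}; x corresponds to column, y to row
#'   (0-based, pixel-centred coordinates are used in downstream tables).
#' @param pixel_size_um physical pixel size in micrometres per pixel.
#' @param case_id case identifier.
#' @param tissue_type one of \code{"epilepsy"}, \code{"meningioma"},
#'   \code{"low_grade"}, \code{"grade_iv"}.
#' @return An object of class \code{multiplex_image}.
#' @examples
#' img <- multiplex_image(
#'   channels = list(Iba1 = matrix(0, 8, 8), P2RY12 = matrix(0, 8, 8)),
#'   pixel_size_um = 0.5, case_id = "case1", tissue_type = "grade_iv")
#' dim(img)
#' @export
multiplex_image <- function(channels, pixel_size_um, case_id = "case",
                            tissue_type = "grade_iv") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == ""))
    stop_myelogate("`channels` must be a named list of matrices",
                   "validation_error")
  if (anyDuplicated(names(channels)))
    stop_myelogate("marker names must be unique", "validation_error")
  if (!all(vapply(channels, is.matrix, logical(1))))
    stop_myelogate("all channels must be matrices", "validation_error")
  dims <- vapply(channels, dim, integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
    stop_myelogate("all channels must share one shape", "validation_error")
  if (!"Iba1" %in% names(channels))
    stop_myelogate("panel must contain Iba1", "validation_error")
  microglial_marker(names(channels))   # validates: exactly one
  highlow_marker(names(channels))      # validates: at most one
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 0,
                       strict_lower = TRUE)
  tissue_type <- match.arg(tissue_type, TISSUE_TYPES)
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         case_id = as.character(case_id), tissue_type = tissue_type),
    class = "multiplex_image")
}

#' @export
dim.multiplex_image <- function(x) dim(x$channels[[1]])

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<multiplex_image> case %s (%s): %d x %d px @ %g um/px\n  markers: %s\n",
    x$case_id, x$tissue_type, d[1], d[2], x$pixel_size_um,
    paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Extract a marker channel
#' @param image a \code{multiplex_image}.
#' @param marker marker name.
#' @return numeric matrix of intensities.
#' @export
get_channel <- function(image, marker) {
  stopifnot(inherits(image, "multiplex_image"))
  if (!marker %in% names(image$channels))
    stop_myelogate(sprintf("marker '%s' not present in image (has: %s)",
                           marker, paste(names(image$channels), collapse = ", ")),
                   "lookup_error")
  image$channels[[marker]]
}
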