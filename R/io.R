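# File formats: multi-page TIFF + JSON sidecar for images, CSV for cell
# tables / ground truth / cohorts, JSON for gating schemes. TIFF samples
# are stored as 32-bit floats scaled into [0, 1]; the scale factor lives in
# the sidecar so intensities round-trip exactly.

#' Write a multiplex image as multi-page TIFF plus JSON sidecar
#'
#' @param image a [multiplex_image()].
#' @param path output TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return invisibly, the sidecar path.
#' @export
write_multiplex_tiff <- function(image, path) {
  stopifnot(inherits(image, "multiplex_image"))
  offset <- min(0, vapply(image$channels, min, numeric(1)))
  scale <- max(1, vapply(image$channels, max, numeric(1)) - offset)
  pages <- lapply(image$channels, function(ch) (ch - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(markers = names(image$channels),
         pixel_size_um = image$pixel_size_um,
         intensity_scale = scale, intensity_offset = offset,
         case_id = image$case_id, tissue_type = image$tissue_type),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a multiplex image written by [write_multiplex_tiff()]
#'
#' @param path TIFF path; the sidecar `<path>.json` must exist.
#' @return a [multiplex_image()].
#' @export
read_multiplex_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$markers))
    stop_myelogate("TIFF page count does not match sidecar marker list",
                   "validation_error")
  offset <- meta$intensity_offset %||% 0
  channels <- lapply(pages, function(p) p * meta$intensity_scale + offset)
  names(channels) <- meta$markers
  multiplex_image(channels, meta$pixel_size_um,
                  case_id = meta$case_id, tissue_type = meta$tissue_type)
}

#' Write / read a cell table as CSV
#' @param table a `cell_table`.
#' @param path CSV path.
#' @export
write_cell_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  as_cell_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read a cohort table as CSV
#' @param records cohort data frame.
#' @param path CSV path.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cohort(out)
  class(out) <- c("cohort", class(out))
  out
}

gate_to_list <- function(g) {
  list(name = g$name, markers = g$markers,
       region = if (g$region$type == "interval")
         list(type = "interval", lo = g$region$lo, hi = g$region$hi)
       else list(type = "polygon",
                 vertices = unname(apply(g$region$vertices, 1, as.list))),
       tissue_scope = g$tissue_scope)
}

gate_from_list <- function(x) {
  if (x$region$type == "interval") {
    hi <- x$region$hi
    if (is.character(hi)) hi <- Inf   # "Inf" survives JSON as a string
    gate(x$name, unlist(x$markers), lo = x$region$lo, hi = hi,
         tissue_scope = x$tissue_scope)
  } else {
    v <- do.call(rbind, lapply(x$region$vertices, unlist))
    gate(x$name, unlist(x$markers), polygon = v,
         tissue_scope = x$tissue_scope)
  }
}

#' Serialize / load a gating scheme as JSON
#' @param scheme a [gating_scheme()].
#' @param path JSON path.
#' @export
write_gating_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "gating_scheme"))
  obj <- list(master_gate = gate_to_list(scheme$master_gate),
              split_gate = gate_to_list(scheme$split_gate),
              highlow_threshold = scheme$highlow_threshold,
              highlow_marker = scheme$highlow_marker)
  if (!is.null(scheme$epilepsy_variant))
    obj$epilepsy_variant <- lapply(scheme$epilepsy_variant, gate_to_list)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_gating_scheme
#' @export
read_gating_scheme <- function(path) {
  x <- jsonlite::read_json(path)
  ev <- NULL
  if (!is.null(x$epilepsy_variant))
    ev <- lapply(x$epilepsy_variant, gate_from_list)
  gating_scheme(gate_from_list(x$master_gate), gate_from_list(x$split_gate),
                highlow_threshold = x$highlow_threshold,
                highlow_marker = x$highlow_marker,
                epilepsy_variant = ev)
}

#' QC scatter of cells in gating space
#'
#' Basic Iba1-vs-marker scatter with the gate thresholds overlaid —
#' the quick visual check that the two populations and the gates land
#' where expected.
#'
#' @param table a `cell_table`.
#' @param scheme optional [gating_scheme()] whose thresholds are drawn.
#' @param marker marker of interest on the x axis (default: the
#'   microglial marker found in the table).
#' @export
plot_gating_qc <- function(table, scheme = NULL, marker = NULL) {
  if (is.null(marker)) marker <- microglial_marker(table_markers(table))
  x <- table[[paste0("mean_", marker)]]
  y <- table[["mean_Iba1"]]
  graphics::plot(x, y, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = paste(marker, "mean intensity"),
                 ylab = "Iba1 mean intensity")
  if (!is.null(scheme)) {
    if (scheme$split_gate$region$type == "interval")
      graphics::abline(v = scheme$split_gate$region$lo, lty = 2, col = "red")
    if (scheme$master_gate$region$type == "interval")
      graphics::abline(h = scheme$master_gate$region$lo, lty = 2,
                       col = "gray40")
  }
  invisible(NULL)
}
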