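# Segmentation: per-marker binary masks, master-mask union, object labeling
# with size filtering, and per-object intensity measurement. This is the
# image-cytometry front end that turns a multiplex image into an FCS-like
# single-cell table.

#' Binarize one marker channel
#'
#' Thresholds a marker channel into a binary mask. A pixel is foreground
#' (1) iff its intensity is >= the resolved threshold. Three threshold
#' methods are provided: a fixed intensity value, Otsu's method, or an
#' intensity quantile of the channel; the resolved threshold is always
#' recorded on the returned mask for auditability.
#'
#' @param image a [multiplex_image()].
#' @param marker marker name present in the image.
#' @param method `"otsu"` (default), `"fixed"`, or `"quantile"`.
#' @param param for `"fixed"`, the intensity threshold (>= 0); for
#'   `"quantile"`, a fraction in (0,1); ignored for `"otsu"`.
#' @return A `binary_mask`: 0/1 integer matrix with attributes
#'   `source_marker`, `threshold_used` and `method`.
#' @export
make_channel_mask <- function(image, marker,
                              method = c("otsu", "fixed", "quantile"),
                              param = NULL) {
  method <- match.arg(method)
  x <- get_channel(image, marker)
  threshold <- switch(method,
    fixed = {
      assert_scalar_number(param, "param", lower = 0)
      param
    },
    quantile = {
      if (is.null(param) || !is.numeric(param) || param <= 0 || param >= 1)
        stop_myelogate("quantile `param` must lie in (0, 1)",
                       "validation_error")
      unname(stats::quantile(x, param, type = 7))
    },
    otsu = {
      rng <- range(x)
      if (rng[1] == rng[2]) rng[2] <- rng[1] + 1  # flat channel: empty mask
      # otsu() returns the last bin below the split; >= keeps foreground
      EBImage::otsu(x, range = rng, levels = 256L)
    })
  binary_mask((x >= threshold) * 1L, source_marker = marker,
              threshold_used = threshold, method = method)
}

binary_mask <- function(m, source_marker = NA_character_,
                        threshold_used = NA_real_, method = NA_character_) {
  storage.mode(m) <- "integer"
  structure(m, source_marker = source_marker,
            threshold_used = threshold_used, method = method,
            class = c("binary_mask", class(m)))
}

#' Union per-marker masks into a master mask
#'
#' Pixelwise logical OR of one or more binary masks. The union of all
#' marker masks is the "master mask" containing all myeloid cells; each
#' connected object in it is subsequently treated as one cell.
#'
#' @param masks list of binary masks (0/1 matrices of one shape).
#' @return A `binary_mask` with `source_marker = "master"`.
#' @export
combine_masks <- function(masks) {
  if (!is.list(masks) || length(masks) < 1L)
    stop_myelogate("`masks` must be a non-empty list", "validation_error")
  dims <- vapply(masks, dim, integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
    stop_myelogate("all masks must share one shape", "validation_error")
  out <- Reduce(function(a, b) (a | b) * 1L, masks)
  binary_mask(out, source_marker = "master",
              threshold_used = NA_real_, method = "union")
}

#' Label objects in a master mask
#'
#' Connected-component labeling of the master mask under 4- or
#' 8-connectivity, discarding components smaller than `min_area_px` and
#' relabeling the survivors consecutively (1..K in raster order).
#'
#' @param master binary mask.
#' @param min_area_px minimum object area in pixels (>= 1). The default of
#'   20 px corresponds to a ~5 um^2 soma cross-section at 0.5 um/px.
#' @param connectivity 4 or 8 (default 8).
#' @return A `labeled_mask`: integer matrix, 0 background, objects 1..K,
#'   with attributes `n_objects` and `min_area_px`.
#' @export
label_objects <- function(master, min_area_px = 20L, connectivity = 8) {
  if (!is.numeric(min_area_px) || min_area_px < 1)
    stop_myelogate("min_area_px must be >= 1", "validation_error")
  lab <- label_components(master, connectivity = connectivity)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab, nbins = max(lab))
    keep <- which(sizes >= min_area_px)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  structure(lab, n_objects = max(lab), min_area_px = as.integer(min_area_px),
            connectivity = connectivity,
            class = c("labeled_mask", class(lab)))
}

#' Measure per-cell mean marker intensities
#'
#' For every labeled object, computes the mean intensity of each marker
#' channel over the object's pixels, the unweighted pixel centroid
#' (0-based; x = column, y = row), and areas in px and um^2. Also computes
#' the stained tissue area used for density normalization.
#'
#' @param labeled a `labeled_mask`.
#' @param image the [multiplex_image()] the mask came from.
#' @param tissue_mask optional binary mask of stained tissue; when supplied,
#'   `tissue_area_mm2` is its foreground area instead of the full frame.
#' @return A `cell_table`: data frame with one row per object and columns
#'   `case_id`, `tissue_type`, `cell_id`, `x_px`, `y_px`, `area_px`,
#'   `area_um2`, `tissue_area_mm2`, and `mean_<marker>` for every channel.
#'   An empty labeling yields a 0-row table (tissue area still recorded).
#' @export
measure_cells <- function(labeled, image, tissue_mask = NULL) {
  stopifnot(inherits(image, "multiplex_image"))
  if (!all(dim(labeled) == dim(image)))
    stop_myelogate("labeled mask shape does not match image",
                   "validation_error")
  px <- image$pixel_size_um
  area_mm2 <- if (is.null(tissue_mask)) {
    prod(dim(labeled)) * px^2 / 1e6
  } else {
    if (!all(dim(tissue_mask) == dim(labeled)))
      stop_myelogate("tissue mask shape mismatch", "validation_error")
    sum(tissue_mask != 0) * px^2 / 1e6
  }
  K <- max(labeled)
  markers <- names(image$channels)
  if (K == 0L) {
    tab <- data.frame(case_id = character(), tissue_type = character(),
                      cell_id = integer(), x_px = numeric(), y_px = numeric(),
                      area_px = integer(), area_um2 = numeric(),
                      tissue_area_mm2 = numeric(),
                      stringsAsFactors = FALSE)
    for (m in markers) tab[[paste0("mean_", m)]] <- numeric()
    return(as_cell_table(tab))
  }
  fg <- which(labeled > 0L)
  lab <- labeled[fg]
  nr <- nrow(labeled)
  rows <- ((fg - 1L) %% nr)        # 0-based y
  cols <- ((fg - 1L) %/% nr)       # 0-based x
  area <- tabulate(lab, nbins = K)
  tab <- data.frame(
    case_id = image$case_id, tissue_type = image$tissue_type,
    cell_id = seq_len(K),
    x_px = as.numeric(rowsum(cols, lab)) / area,
    y_px = as.numeric(rowsum(rows, lab)) / area,
    area_px = area,
    area_um2 = area * px^2,
    tissue_area_mm2 = area_mm2,
    stringsAsFactors = FALSE)
  for (m in markers)
    tab[[paste0("mean_", m)]] <-
      as.numeric(rowsum(image$channels[[m]][fg], lab)) / area
  as_cell_table(tab)
}

as_cell_table <- function(df) {
  class(df) <- unique(c("cell_table", class(df)))
  df
}

#' Marker columns of a cell table
#' @param table a `cell_table`.
#' @return marker names for which a `mean_<marker>` column exists.
#' @export
table_markers <- function(table) {
  sub("^mean_", "", grep("^mean_", names(table), value = TRUE))
}

#' Pool single-cell tables across cases
#'
#' Row-concatenates per-case cell tables into one pooled table, preserving
#' case provenance, so that cells from all cases can be gated together on a
#' shared intensity scale.
#'
#' @param tables list of `cell_table`s with identical columns.
#' @return Pooled `cell_table`. Duplicate `(case_id, cell_id)` pairs raise
#'   an integrity error.
#' @export
pool_cases <- function(tables) {
  if (!is.list(tables) || !length(tables))
    stop_myelogate("`tables` must be a non-empty list", "validation_error")
  cols <- lapply(tables, names)
  if (length(unique(vapply(cols, paste, character(1), collapse = "\r"))) != 1L)
    stop_myelogate("cell tables have differing columns", "validation_error")
  pooled <- do.call(rbind, lapply(tables, as.data.frame))
  rownames(pooled) <- NULL
  key <- paste(pooled$case_id, pooled$cell_id, sep = "\r")
  if (anyDuplicated(key))
    stop_myelogate("duplicate (case_id, cell_id) pairs after pooling",
                   "integrity_error")
  as_cell_table(pooled)
}
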