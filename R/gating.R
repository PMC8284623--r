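# Flow-cytometry-style gating of the single-cell intensity table: a debris
# exclusion master gate on Iba1 intensity, a microglia/TAM split on the
# microglial-marker intensity, and a high/low split on CD14 or CD163
# calibrated from negative-control (epilepsy) staining. Gate intervals are
# closed-left, open-right; a cell exactly on a 1-D threshold goes to the
# upper region.

#' Define a gate in intensity space
#'
#' A gate is either a 1-D interval `[lo, hi)` on one marker's mean
#' intensity, or a 2-D polygon over two markers (vertices in intensity
#' space; membership by even-odd ray casting, boundary counts as inside).
#'
#' @param name gate name.
#' @param markers one marker name (interval gate) or two (polygon gate).
#' @param lo,hi interval bounds (1-D gates); `hi` may be `Inf`.
#' @param polygon 2-column matrix of vertices (2-D gates), >= 3 rows,
#'   columns matching `markers`.
#' @param tissue_scope `"tumor"`, `"epilepsy"`, or `"all"`.
#' @return A `gate` object.
#' @export
gate <- function(name, markers, lo = NULL, hi = Inf, polygon = NULL,
                 tissue_scope = c("all", "tumor", "epilepsy")) {
  tissue_scope <- match.arg(tissue_scope)
  if (is.null(polygon)) {
    if (length(markers) != 1L)
      stop_myelogate("interval gate needs exactly one marker",
                     "validation_error")
    assert_scalar_number(lo, "lo")
    if (!is.numeric(hi) || length(hi) != 1L || is.na(hi))
      stop_myelogate("`hi` must be a number (possibly Inf)",
                     "validation_error")
    if (lo >= hi)
      stop_myelogate("interval gate requires lo < hi", "validation_error")
    region <- list(type = "interval", lo = lo, hi = hi)
  } else {
    if (length(markers) != 2L)
      stop_myelogate("polygon gate needs exactly two markers",
                     "validation_error")
    polygon <- as.matrix(polygon)
    if (nrow(polygon) < 3L || ncol(polygon) != 2L)
      stop_myelogate("polygon needs >= 3 vertices and 2 columns",
                     "validation_error")
    if (polygon_self_intersects(polygon))
      stop_myelogate("polygon must be simple (non-self-intersecting)",
                     "validation_error")
    region <- list(type = "polygon", vertices = polygon)
  }
  structure(list(name = name, markers = markers, region = region,
                 tissue_scope = tissue_scope), class = "gate")
}

# segment-intersection test over all non-adjacent edge pairs
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  seg <- function(i) rbind(v[i, ], v[if (i == n) 1L else i + 1L, ])
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(p1, p2, p3, p4) {
    d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
    d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) <= 1L || (i == 1L && j == n) || (i == n && j == 1L)) next
    si <- seg(i); sj <- seg(j)
    if (intersects(si[1, ], si[2, ], sj[1, ], sj[2, ])) return(TRUE)
  }
  FALSE
}

#' Does each cell fall inside a gate?
#' @param gate a [gate()].
#' @param table a `cell_table`.
#' @return logical vector, one entry per row of `table`.
#' @export
gate_membership <- function(gate, table) {
  cols <- paste0("mean_", gate$markers)
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop_myelogate(paste("cell table lacks marker column(s):",
                         paste(miss, collapse = ", ")), "schema_error")
  if (gate$region$type == "interval") {
    v <- table[[cols[1]]]
    v >= gate$region$lo & v < gate$region$hi
  } else {
    as.logical(pracma::inpolygon(
      table[[cols[1]]], table[[cols[2]]],
      gate$region$vertices[, 1], gate$region$vertices[, 2],
      boundary = TRUE))
  }
}

#' Hierarchical gating scheme
#'
#' Bundles the debris-exclusion master gate (on Iba1), the microglia/TAM
#' split gate (on the microglial marker) and an optional CD14/CD163
#' high/low gate, with separate tumor and epilepsy variants where staining
#' differences require them. Cells inside the split gate's region are
#' called microglia; non-debris cells outside it are TAMs, so the two
#' classes partition the master-gated space by construction.
#'
#' @param master_gate [gate()] on Iba1 defining non-debris ("total") cells.
#' @param split_gate [gate()] on the microglial marker defining microglia.
#' @param highlow_threshold optional intensity threshold for the CD14/CD163
#'   high/low split (typically from [derive_control_threshold()]).
#' @param highlow_marker marker the threshold applies to.
#' @param epilepsy_variant optional named list with replacement
#'   `master_gate`/`split_gate` applied to epilepsy-tissue tables.
#' @return A `gating_scheme`.
#' @export
gating_scheme <- function(master_gate, split_gate,
                          highlow_threshold = NULL, highlow_marker = NULL,
                          epilepsy_variant = NULL) {
  stopifnot(inherits(master_gate, "gate"), inherits(split_gate, "gate"))
  if (!identical(master_gate$markers, "Iba1"))
    stop_myelogate("master gate must act on Iba1", "validation_error")
  if (!is.null(highlow_threshold))
    assert_scalar_number(highlow_threshold, "highlow_threshold", lower = 0)
  structure(list(master_gate = master_gate, split_gate = split_gate,
                 highlow_threshold = highlow_threshold,
                 highlow_marker = highlow_marker,
                 epilepsy_variant = epilepsy_variant),
            class = "gating_scheme")
}

scheme_for <- function(scheme, tissue_type) {
  if (identical(tissue_type, "epilepsy") &&
      !is.null(scheme$epilepsy_variant)) {
    out <- scheme
    for (nm in names(scheme$epilepsy_variant))
      out[[nm]] <- scheme$epilepsy_variant[[nm]]
    out
  } else scheme
}

new_population_call <- function(table, primary, secondary = NULL,
                                provenance = list()) {
  stopifnot(length(primary) == nrow(table))
  out <- data.frame(case_id = table$case_id, cell_id = table$cell_id,
                    primary_label = primary, stringsAsFactors = FALSE)
  out$secondary_label <- if (is.null(secondary))
    rep(NA_character_, nrow(table)) else secondary
  structure(out, provenance = provenance,
            class = c("population_call", class(out)))
}

#' Apply the debris-exclusion master gate
#'
#' Marks each cell as `total` (inside the Iba1 master region: a myeloid
#' cell) or `debris`. Tissue-specific gate variants are honored via the
#' table's `tissue_type` column.
#'
#' @param table a `cell_table`.
#' @param scheme a [gating_scheme()].
#' @return A `population_call` with `primary_label` in {debris, total}.
#' @export
apply_master_gate <- function(table, scheme) {
  stopifnot(inherits(scheme, "gating_scheme"))
  primary <- character(nrow(table))
  for (tt in unique(table$tissue_type)) {
    rows <- table$tissue_type == tt
    sc <- scheme_for(scheme, tt)
    inside <- gate_membership(sc$master_gate, table[rows, , drop = FALSE])
    primary[rows] <- ifelse(inside, "total", "debris")
  }
  new_population_call(table, primary,
                      provenance = list(master_gate = scheme$master_gate$name))
}

#' Classify non-debris cells as microglia or TAMs
#'
#' Applies the master gate, then splits non-debris cells on the microglial
#' marker: inside the split region = microglia (Iba1+ P2RY12+/TMEM119+),
#' outside = TAM (Iba1+ P2RY12-/TMEM119-). The two classes partition the
#' master-gated cells.
#'
#' @param table a `cell_table`.
#' @param scheme a [gating_scheme()].
#' @return A `population_call` with `primary_label` in
#'   {debris, microglia, tam}.
#' @export
classify_microglia_tam <- function(table, scheme) {
  calls <- apply_master_gate(table, scheme)
  primary <- calls$primary_label
  for (tt in unique(table$tissue_type)) {
    rows <- which(table$tissue_type == tt & primary != "debris")
    if (!length(rows)) next
    sc <- scheme_for(scheme, tt)
    inside <- gate_membership(sc$split_gate, table[rows, , drop = FALSE])
    primary[rows] <- ifelse(inside, "microglia", "tam")
  }
  secondary <- rep(NA_character_, nrow(table))
  if (!is.null(scheme$highlow_threshold)) {
    hl <- classify_high_low(table, scheme$highlow_marker,
                            scheme$highlow_threshold,
                            non_debris = primary != "debris")
    secondary <- hl
  }
  new_population_call(table, primary, secondary,
                      provenance = list(master_gate = scheme$master_gate$name,
                                        split_gate = scheme$split_gate$name,
                                        highlow_threshold =
                                          scheme$highlow_threshold))
}

#' Calibrate a marker-positivity threshold from negative-control tissue
#'
#' CD14/CD163 show a continuum rather than two populations, so the
#' high/low cut is taken from negative-control (epilepsy) staining: the
#' stated quantile (default 0.99) of the pooled control cells' marker
#' means, by the type-7 linear-interpolation quantile convention.
#'
#' @param control_tables list of epilepsy-tissue `cell_table`s.
#' @param marker `"CD14"` or `"CD163"`.
#' @param quantile fraction in (0, 1); default 0.99.
#' @return numeric threshold with attributes `n_control` and `quantile`.
#' @export
derive_control_threshold <- function(control_tables, marker,
                                     quantile = 0.99) {
  if (!marker %in% TAM_MARKERS)
    stop_myelogate("high/low marker must be CD14 or CD163",
                   "validation_error")
  if (!is.numeric(quantile) || quantile <= 0 || quantile >= 1)
    stop_myelogate("quantile must lie strictly in (0, 1)",
                   "validation_error")
  if (inherits(control_tables, "data.frame"))
    control_tables <- list(control_tables)
  col <- paste0("mean_", marker)
  vals <- unlist(lapply(control_tables, function(tb) {
    if (!col %in% names(tb))
      stop_myelogate(paste("control table lacks", col), "schema_error")
    tb[[col]]
  }), use.names = FALSE)
  if (!length(vals))
    stop_myelogate("no control cells available to derive a threshold",
                   "insufficient_data_error")
  th <- unname(stats::quantile(vals, quantile, type = 7))
  structure(th, n_control = length(vals), quantile = quantile)
}

#' Split non-debris cells into marker-high and marker-low
#'
#' @param table a `cell_table`.
#' @param marker `"CD14"` or `"CD163"`.
#' @param threshold intensity threshold (>= 0); marker mean >= threshold is
#'   `cd_high`, below is `cd_low`.
#' @param non_debris logical vector of cells to classify (default: all).
#' @return character vector of secondary labels (`NA` for debris cells).
#' @export
classify_high_low <- function(table, marker, threshold,
                              non_debris = rep(TRUE, nrow(table))) {
  col <- paste0("mean_", marker)
  if (!col %in% names(table))
    stop_myelogate(paste("cell table lacks", col), "schema_error")
  assert_scalar_number(as.numeric(threshold), "threshold", lower = 0)
  out <- rep(NA_character_, nrow(table))
  v <- table[[col]][non_debris]
  out[non_debris] <- ifelse(v >= threshold, "cd_high", "cd_low")
  out
}

#' Per-case gate counts
#'
#' Tabulates debris / microglia / TAM / cd_high / cd_low counts per case
#' and checks the partition arithmetic (microglia + tam = non-debris;
#' cd_high + cd_low = non-debris when the marker is gated).
#'
#' @param calls a `population_call`.
#' @param table the `cell_table` the calls were computed from.
#' @return data frame, one row per case.
#' @export
gate_report <- function(calls, table) {
  if (nrow(calls) != nrow(table) ||
      !all(calls$case_id == table$case_id & calls$cell_id == table$cell_id))
    stop_myelogate("calls do not cover the table rows one-to-one",
                   "integrity_error")
  split_rows <- split(seq_len(nrow(table)), table$case_id)
  if (!length(split_rows))
    return(data.frame(case_id = character(), total = integer(),
                      debris = integer(), microglia = integer(),
                      tam = integer(), cd_high = integer(),
                      cd_low = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(names(split_rows), function(cid) {
    i <- split_rows[[cid]]
    pl <- calls$primary_label[i]; sl <- calls$secondary_label[i]
    data.frame(case_id = cid,
               total = sum(pl != "debris"), debris = sum(pl == "debris"),
               microglia = sum(pl == "microglia"), tam = sum(pl == "tam"),
               cd_high = sum(sl == "cd_high", na.rm = TRUE),
               cd_low = sum(sl == "cd_low", na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Suggest a microglia/TAM split threshold from a bimodal distribution
#'
#' Optional helper (an extension over manual gate placement): fits a
#' 2-component Gaussian mixture to the pooled microglial-marker means and
#' returns the intensity at which the two components' posterior
#' probabilities cross between the component means. Always overridable;
#' the suggested value carries provenance attributes.
#'
#' @param values numeric vector of microglial-marker cell means.
#' @return threshold with attributes `method`, `component_means`.
#' @export
suggest_split_threshold <- function(values) {
  if (length(values) < 10L)
    stop_myelogate("need >= 10 cells to suggest a split",
                   "insufficient_data_error")
  # deterministic init from the quartiles keeps the helper a pure function
  init <- stats::kmeans(values,
                        centers = stats::quantile(values, c(0.25, 0.75)))
  z0 <- mclust::unmap(init$cluster)
  fit <- mclust::meV(data = values, z = z0, prior = NULL,
                     control = mclust::emControl())
  mu <- as.numeric(fit$parameters$mean)
  sd2 <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sd2) == 1L) sd2 <- rep(sd2, 2)
  pro <- as.numeric(fit$parameters$pro)
  lo <- which.min(mu); hi <- which.max(mu)
  # crossing of the two weighted component densities between the means
  dens_diff <- function(x)
    pro[lo] * stats::dnorm(x, mu[lo], sd2[lo]) -
      pro[hi] * stats::dnorm(x, mu[hi], sd2[hi])
  th <- tryCatch(stats::uniroot(dens_diff, sort(mu))$root,
                 error = function(e) mean(mu))
  structure(th, method = "gmm2_posterior_crossing",
            component_means = sort(mu))
}
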