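# Per-case population summaries and the group comparisons run on them:
# proportions of total gated cells, densities in cells/mm^2, the
# microglia:TAM ratio, per-population mean single-cell intensities, and a
# per-marker global-expression index (integrated intensity normalized to
# myeloid cell density).

#' Summarize one case's gated cell populations
#'
#' Computes, for a single case's cell table and gating calls: total gated
#' (non-debris) count, microglia/TAM counts and their proportions of total
#' gated cells, densities in cells/mm^2 of stained tissue, the
#' microglia:TAM ratio, optional cd_high/cd_low counts and proportions,
#' per-population per-marker mean single-cell average intensities, and per
#' microglial-marker the global expression index
#' `sum(mean intensity x area_px over non-debris cells) / density_total`.
#'
#' @param table a `cell_table` for one case (one `tissue_area_mm2`).
#' @param calls matching `population_call`.
#' @param zero_tam_ratio convention for microglia:TAM with 0 TAMs:
#'   `"inf"` (default; `Inf` sentinel, flagged via attribute) or
#'   `"continuity"` (adds 0.5 to both counts).
#' @return one-row data frame of class `case_summary`.
#' @export
summarize_case <- function(table, calls,
                           zero_tam_ratio = c("inf", "continuity")) {
  zero_tam_ratio <- match.arg(zero_tam_ratio)
  if (length(unique(table$case_id)) != 1L)
    stop_myelogate("summarize_case expects a single case; see pool_cases/average_replicates",
                   "validation_error")
  area <- unique(table$tissue_area_mm2)
  if (length(area) != 1L || !is.finite(area) || area <= 0)
    stop_myelogate("table must carry one positive tissue_area_mm2",
                   "validation_error")
  rep_report <- gate_report(calls, table)
  n_mg <- rep_report$microglia; n_tam <- rep_report$tam
  total <- rep_report$total
  ratio <- if (n_tam > 0) {
    n_mg / n_tam
  } else if (zero_tam_ratio == "continuity") {
    (n_mg + 0.5) / 0.5
  } else Inf
  out <- data.frame(
    case_id = table$case_id[1] %||% rep_report$case_id,
    tissue_type = table$tissue_type[1],
    total_gated = total, microglia_count = n_mg, tam_count = n_tam,
    prop_microglia = if (total > 0) n_mg / total else NA_real_,
    prop_tam = if (total > 0) n_tam / total else NA_real_,
    density_total = total / area,
    density_microglia = n_mg / area,
    density_tam = n_tam / area,
    ratio_mg_tam = ratio,
    tissue_area_mm2 = area,
    stringsAsFactors = FALSE)
  if (rep_report$cd_high + rep_report$cd_low > 0) {
    out$cd_high_count <- rep_report$cd_high
    out$cd_low_count <- rep_report$cd_low
    out$prop_cd_high <- rep_report$cd_high / total
    out$prop_cd_low <- rep_report$cd_low / total
  }
  # per-population per-marker mean of the single-cell average intensities
  for (m in table_markers(table)) {
    col <- paste0("mean_", m)
    for (pop in c("microglia", "tam")) {
      sel <- calls$primary_label == pop
      out[[sprintf("mean_%s_%s", m, pop)]] <-
        if (any(sel)) mean(table[[col]][sel]) else NA_real_
    }
  }
  # global expression index for microglial marker(s): integrated intensity
  # (sum over non-debris cells of mean x area_px) normalized to density
  nd <- calls$primary_label != "debris"
  for (m in intersect(MICROGLIAL_MARKERS, table_markers(table))) {
    integrated <- sum(table[[paste0("mean_", m)]][nd] * table$area_px[nd])
    out[[paste0("gei_", m)]] <-
      if (total > 0) integrated / (total / area) else NA_real_
  }
  class(out) <- c("case_summary", class(out))
  out
}

#' Average repeated stainings of one case
#'
#' Repeated-staining replicates of a single case are collapsed to one row
#' per case by averaging all numeric summary fields, before any cross-case
#' statistics.
#'
#' @param summaries data frame of stacked [summarize_case()] rows (one per
#'   replicate image).
#' @return data frame with one row per `case_id`; attribute `n_replicates`
#'   records the collapse.
#' @export
average_replicates <- function(summaries) {
  num <- vapply(summaries, is.numeric, logical(1))
  split_i <- split(seq_len(nrow(summaries)), summaries$case_id)
  out <- do.call(rbind, lapply(split_i, function(i) {
    row <- summaries[i[1], , drop = FALSE]
    for (cn in names(summaries)[num])
      row[[cn]] <- mean(summaries[[cn]][i])
    row
  }))
  rownames(out) <- NULL
  attr(out, "n_replicates") <- vapply(split_i, length, integer(1))
  out
}

#' Bind case summaries into one table
#' @param summaries list of one-row `case_summary` data frames.
#' @return stacked data frame.
#' @export
bind_summaries <- function(summaries) {
  out <- do.call(rbind, lapply(summaries, as.data.frame))
  rownames(out) <- NULL
  out
}
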