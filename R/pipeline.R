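# End-to-end conveniences: image -> cell table, and the median-split
# survival analysis chain (exclusions -> split -> KM -> log-rank ->
# univariate Cox -> AIC selection -> multivariate Cox).

#' Segment a multiplex image into a single-cell table
#'
#' Runs the full measurement stage: one binary mask per marker channel,
#' union into the master mask, connected-component labeling with size
#' filtering, and per-object mean-intensity measurement.
#'
#' @param image a [multiplex_image()].
#' @param method,param threshold method and parameter forwarded to
#'   [make_channel_mask()] for every channel (per-channel control is
#'   available by calling the stage functions directly).
#' @param min_area_px,connectivity forwarded to [label_objects()].
#' @param tissue_mask optional stained-tissue mask for area normalization.
#' @return a `cell_table`; attribute `thresholds` records the per-channel
#'   thresholds used.
#' @export
segment_image <- function(image, method = "otsu", param = NULL,
                          min_area_px = 20L, connectivity = 8,
                          tissue_mask = NULL) {
  masks <- lapply(names(image$channels), function(m)
    make_channel_mask(image, m, method = method, param = param))
  master <- combine_masks(masks)
  labeled <- label_objects(master, min_area_px = min_area_px,
                           connectivity = connectivity)
  out <- measure_cells(labeled, image, tissue_mask = tissue_mask)
  attr(out, "thresholds") <- stats::setNames(
    vapply(masks, attr, numeric(1), "threshold_used"),
    names(image$channels))
  out
}

#' Median-split survival analysis of a per-case metric
#'
#' The outcome-analysis chain applied to a cohort table: optional case
#' exclusions (IDH1-mutant cases by default), median split of the chosen
#' metric into high/low groups, Kaplan-Meier curves and log-rank test,
#' univariate Cox on the group indicator, AIC selection over the group
#' indicator plus adjustment covariates, and the multivariate Cox fit on
#' the selected set.
#'
#' @param records cohort data frame (`time_months`, `event`, metric,
#'   adjustment covariates).
#' @param metric per-case metric to median-split (default `"ratio"`).
#' @param adjust character vector of adjustment covariates (default
#'   `"mgmt_methylated"`).
#' @param exclusions rules for [exclude_cases()]; NULL disables.
#' @param force_multivariate when TRUE the multivariate model always
#'   contains the group indicator plus all adjustment covariates,
#'   regardless of the AIC selection (which is still reported).
#' @return list: `records` (post-exclusion, with group column), `split`,
#'   `km`, `logrank`, `cox_uni`, `selection`, `cox_multi` (NULL when the
#'   selected set is empty and `force_multivariate` is FALSE).
#' @export
ratio_survival_analysis <- function(records, metric = "ratio",
                                    adjust = "mgmt_methylated",
                                    exclusions = list(idh1_mutant = 1L),
                                    force_multivariate = FALSE) {
  if (!is.null(exclusions) &&
      all(names(exclusions) %in% names(records)))
    records <- exclude_cases(records, exclusions)
  records <- median_split(records, metric)
  group_col <- paste0("group_", metric)
  # numeric 0/1 indicator so Cox output is the high-vs-low hazard ratio
  records$..high <- as.integer(records[[group_col]] == "high")
  ind <- paste0(metric, "_high")
  names(records)[names(records) == "..high"] <- ind
  km <- km_estimate(records, group_col)
  lr <- logrank_test(records, group_col)
  cox_uni <- cox_univariate(records, ind)
  adjust <- intersect(adjust, names(records))
  sel <- aic_select(records, c(ind, adjust))
  multi_covs <- if (force_multivariate) c(ind, adjust) else sel$selected
  cox_multi <- if (length(multi_covs))
    cox_multivariate(records, multi_covs) else NULL
  list(records = records, split = attr(records, "split"), km = km,
       logrank = lr, cox_uni = cox_uni, selection = sel,
       cox_multi = cox_multi, group_col = group_col, indicator = ind)
}
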