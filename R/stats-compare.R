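# Thin wrappers around the standard group-comparison tests used on
# per-case summaries: Mann-Whitney U, paired t, and two-way ANOVA with
# Tukey or Sidak multiple-comparison follow-up, plus the Shapiro-Wilk /
# F-test assumption gate that decides between parametric and
# nonparametric routes.

#' Compare a per-case metric between groups
#'
#' Runs the named standard test on a metric of the per-case summary table.
#' For the two-way designs, `metric` names two population-specific columns
#' (e.g. `prop_microglia` and `prop_tam`); the table is melted into a long
#' format with factors `population` and `group` and analyzed by two-way
#' ANOVA (type-II sums of squares for unbalanced designs) with Tukey or
#' Sidak-adjusted pairwise comparisons.
#'
#' @param summaries per-case summary data frame (replicates already
#'   collapsed by [average_replicates()]).
#' @param metric one column name (Mann-Whitney/paired t) or two (two-way
#'   designs).
#' @param design `"mann_whitney_u"`, `"paired_t"`,
#'   `"two_way_anova_tukey"`, or `"two_way_anova_sidak"`.
#' @param group grouping column, default `"tissue_type"`.
#' @return list of class `group_comparison`: `test`, `groups`, `statistic`,
#'   `p_value`, `group_stats` (n, mean, sd per group), and for ANOVA
#'   designs `anova_table` and `pairwise`.
#' @export
compare_populations <- function(summaries, metric,
                                design = c("mann_whitney_u", "paired_t",
                                           "two_way_anova_tukey",
                                           "two_way_anova_sidak"),
                                group = "tissue_type") {
  design <- match.arg(design)
  if (!group %in% names(summaries))
    stop_myelogate(sprintf("grouping column '%s' missing", group),
                   "validation_error")
  miss <- setdiff(metric, names(summaries))
  if (length(miss))
    stop_myelogate(paste("metric column(s) missing:",
                         paste(miss, collapse = ", ")), "validation_error")
  g <- factor(summaries[[group]])
  if (design %in% c("mann_whitney_u", "paired_t")) {
    if (length(metric) != 1L)
      stop_myelogate("this design takes a single metric column",
                     "validation_error")
    v <- summaries[[metric]]
    keep <- is.finite(v)
    v <- v[keep]; g2 <- droplevels(g[keep])
    if (nlevels(g2) != 2L)
      stop_myelogate("two-group tests require exactly 2 groups",
                     "validation_error")
    sizes <- table(g2)
    if (any(sizes < 1L))
      stop_myelogate(sprintf("group '%s' has no cases",
                             names(sizes)[sizes < 1][1]),
                     "insufficient_data_error")
    x <- v[g2 == levels(g2)[1]]; y <- v[g2 == levels(g2)[2]]
    ht <- if (design == "mann_whitney_u") {
      suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    } else {
      if (length(x) != length(y))
        stop_myelogate("paired t-test requires equal group sizes (matched cases)",
                       "validation_error")
      stats::t.test(x, y, paired = TRUE)
    }
    res <- list(test = design, groups = levels(g2),
                statistic = unname(ht$statistic), p_value = ht$p.value,
                group_stats = data.frame(
                  group = levels(g2), n = as.integer(sizes),
                  mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y))))
  } else {
    if (length(metric) != 2L)
      stop_myelogate("two-way designs take two metric columns (the two populations)",
                     "validation_error")
    long <- data.frame(
      value = c(summaries[[metric[1]]], summaries[[metric[2]]]),
      population = factor(rep(metric, each = nrow(summaries))),
      group = factor(rep(g, 2)))
    long <- long[is.finite(long$value), , drop = FALSE]
    sizes <- table(long$group, long$population)
    if (any(rowSums(sizes) < 2L))
      stop_myelogate(sprintf("group '%s' has < 2 observations",
                             rownames(sizes)[rowSums(sizes) < 2][1]),
                     "insufficient_data_error")
    fit <- stats::aov(value ~ population * group, data = long)
    a2 <- car::Anova(fit, type = 2)
    inter <- "population:group"
    res <- list(test = design, groups = levels(long$group),
                statistic = a2[inter, "F value"],
                p_value = a2[inter, "Pr(>F)"],
                anova_table = a2,
                group_stats = do.call(rbind, lapply(
                  split(long$value, interaction(long$group, long$population)),
                  function(v) data.frame(n = length(v), mean = mean(v),
                                         sd = stats::sd(v)))))
    if (design == "two_way_anova_tukey") {
      res$pairwise <- stats::TukeyHSD(fit, "group")$group
    } else {
      # pairwise Welch t-tests with Sidak family-wise adjustment
      lev <- levels(long$group)
      prs <- utils::combn(lev, 2, simplify = FALSE)
      m <- length(prs)
      res$pairwise <- do.call(rbind, lapply(prs, function(pr) {
        p <- stats::t.test(long$value[long$group == pr[1]],
                           long$value[long$group == pr[2]])$p.value
        data.frame(comparison = paste(pr, collapse = "-"),
                   p_raw = p, p_sidak = 1 - (1 - p)^m,
                   stringsAsFactors = FALSE)
      }))
    }
  }
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  print(x$group_stats)
  invisible(x)
}

#' Normality and equal-variance gate
#'
#' Runs the Shapiro-Wilk normality test per group and (for two groups) the
#' F-test of equal variance, and records which downstream route the
#' results support: parametric when no group rejects normality, otherwise
#' nonparametric. Groups with n < 3 (or zero variance) cannot be tested
#' and default to the nonparametric route with a warning.
#'
#' @param values_by_group named list of numeric vectors.
#' @param alpha rejection level for the assumption checks (default 0.05).
#' @return list: `shapiro_p` (named, NA where untestable),
#'   `variance_ratio_p` (two groups only), `recommended` route.
#' @export
normality_gate <- function(values_by_group, alpha = 0.05) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 1L)
  shapiro_p <- vapply(values_by_group, function(v) {
    if (length(v) < 3L || stats::sd(v) == 0) {
      warning("group untestable for normality (n < 3 or constant); ",
              "defaulting to nonparametric route", call. = FALSE)
      return(NA_real_)
    }
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  var_p <- NA_real_
  if (length(values_by_group) == 2L &&
      all(vapply(values_by_group, length, integer(1)) >= 2L))
    var_p <- stats::var.test(values_by_group[[1]],
                             values_by_group[[2]])$p.value
  recommended <- if (anyNA(shapiro_p) || any(shapiro_p < alpha))
    "nonparametric" else "parametric"
  list(shapiro_p = shapiro_p, variance_ratio_p = var_p,
       recommended = recommended)
}
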