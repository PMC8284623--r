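# Outcome analysis: case exclusion, median-split cohort assignment,
# Kaplan-Meier estimation, log-rank comparison, univariate Cox screening,
# AIC-guided variable selection and multivariate Cox. Model fitting is
# delegated to the survival package (Efron handling of tied event times);
# this module supplies the cohort bookkeeping, the median-split convention
# and the selection logic around it.

check_cohort <- function(records) {
  need <- c("time_months", "event")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_myelogate(paste("cohort lacks columns:", paste(miss, collapse = ", ")),
                   "validation_error")
  if (any(!is.finite(records$time_months)) || any(records$time_months <= 0))
    stop_myelogate("survival times must be finite and positive",
                   "validation_error")
  if (!all(records$event %in% c(0L, 1L)))
    stop_myelogate("event indicator must be 0/1", "validation_error")
  invisible(records)
}

#' Exclude cases by covariate rules
#'
#' Removes records matching any exclusion rule and logs the exclusions.
#' The standard use is dropping IDH1-mutant glioblastoma cases, which are
#' a biologically distinct entity, before survival analysis.
#'
#' @param records cohort data frame.
#' @param rules named list: covariate name -> value(s) to exclude; a record
#'   is removed if its covariate equals any listed value.
#' @return records with matching rows removed; attribute `exclusions` holds
#'   a data frame of case_id and reason. Excluding everything triggers a
#'   hard warning.
#' @export
exclude_cases <- function(records, rules = list(idh1_mutant = 1L)) {
  check_cohort(records)
  if (!length(rules)) return(records)
  bad <- setdiff(names(rules), names(records))
  if (length(bad))
    stop_myelogate(paste("exclusion rule references unknown covariate:",
                         paste(bad, collapse = ", ")), "config_error")
  drop <- rep(FALSE, nrow(records))
  reason <- character(nrow(records))
  for (cov in names(rules)) {
    hit <- records[[cov]] %in% rules[[cov]]
    reason[hit & !drop] <- sprintf("%s in {%s}", cov,
                                   paste(rules[[cov]], collapse = ","))
    drop <- drop | hit
  }
  out <- records[!drop, , drop = FALSE]
  attr(out, "exclusions") <- data.frame(
    case_id = records$case_id[drop], reason = reason[drop],
    stringsAsFactors = FALSE)
  if (!nrow(out))
    warning("exclusion rules removed every record", call. = FALSE)
  out
}

#' Median split of a per-case metric into high/low cohorts
#'
#' Dichotomizes `metric` at its cohort median: values above the median go
#' to "high", values below to "low". Values exactly at the median go to
#' "low" by default (`ties = "low"`); the convention is switchable and the
#' per-group n is always recorded.
#'
#' @param records cohort data frame.
#' @param metric name of a numeric column.
#' @param ties `"low"` (default) or `"high"`: side receiving values equal
#'   to the median.
#' @return records with an added factor column `group_<metric>` (levels
#'   low, high) and attribute `split` (median, n per group).
#' @export
median_split <- function(records, metric, ties = c("low", "high")) {
  ties <- match.arg(ties)
  check_cohort(records)
  if (!metric %in% names(records))
    stop_myelogate(sprintf("metric '%s' not in records", metric),
                   "validation_error")
  v <- records[[metric]]
  if (!is.numeric(v) || any(!is.finite(v)))
    stop_myelogate("metric must be numeric and finite for all records",
                   "validation_error")
  med <- stats::median(v)
  if (all(v == v[1]))
    stop_myelogate("all metric values identical; median split is degenerate",
                   "degenerate_split_error")
  grp <- ifelse(v > med, "high", ifelse(v < med, "low", ties))
  col <- paste0("group_", metric)
  records[[col]] <- factor(grp, levels = c("low", "high"))
  attr(records, "split") <- list(metric = metric, median = med, ties = ties,
                                 n_low = sum(grp == "low"),
                                 n_high = sum(grp == "high"))
  records
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimate per group of `group_col` (or a single pooled
#' curve when `group_col` is NULL). Median survival is the earliest
#' observed time at which the estimated survival drops to <= 0.5, and is
#' undefined (NA) when the curve never reaches 0.5.
#'
#' @param records cohort data frame.
#' @param group_col name of a grouping column, or NULL.
#' @return list of class `km_curve_set`: per group, a data frame with
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`, plus `median`.
#' @export
km_estimate <- function(records, group_col = NULL) {
  check_cohort(records)
  if (is.null(group_col)) {
    grp <- factor(rep("all", nrow(records)))
  } else {
    if (!group_col %in% names(records))
      stop_myelogate(sprintf("group column '%s' missing", group_col),
                     "validation_error")
    grp <- factor(records[[group_col]])
  }
  out <- list()
  for (g in levels(grp)) {
    sub <- records[grp == g, , drop = FALSE]
    if (!nrow(sub)) next
    fit <- survival::survfit(
      survival::Surv(time_months, event) ~ 1, data = sub)
    curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        surv = fit$surv)
    reached <- curve$time[curve$surv <= 0.5 & curve$n_event > 0]
    out[[g]] <- list(curve = curve, n = nrow(sub),
                     median = if (length(reached)) min(reached) else NA_real_)
  }
  structure(out, class = "km_curve_set", group_col = group_col)
}

#' Log-rank test between two survival groups
#'
#' @param records cohort data frame.
#' @param group_col grouping column with exactly two observed levels.
#' @return list: `chisq`, `df` (= 1), `p`, per-group observed/expected
#'   event counts.
#' @export
logrank_test <- function(records, group_col) {
  check_cohort(records)
  if (!group_col %in% names(records))
    stop_myelogate(sprintf("group column '%s' missing", group_col),
                   "validation_error")
  g <- factor(records[[group_col]])
  g <- droplevels(g)
  if (nlevels(g) != 2L)
    stop_myelogate("log-rank comparison requires exactly 2 groups",
                   "validation_error")
  if (sum(records$event) < 1L)
    stop_myelogate("log-rank requires at least one event", "validation_error")
  records$..g <- g
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ ..g,
                           data = records)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), df = 1L, p = p,
       observed = sd$obs, expected = sd$exp)
}

cox_result <- function(fit, covariates, flagged = FALSE, note = NA_character_) {
  s <- summary(fit)
  ci <- s$conf.int
  co <- s$coefficients
  res <- data.frame(
    covariate = rownames(co),
    hr = unname(co[, "exp(coef)"]),
    ci_lower = unname(ci[, "lower .95"]),
    ci_upper = unname(ci[, "upper .95"]),
    p = unname(co[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE)
  structure(list(
    covariates = covariates, table = res,
    loglik = fit$loglik[length(fit$loglik)],
    aic = stats::AIC(fit),
    n = fit$n, n_events = fit$nevent,
    converged = fit$iter[1] < 20L,  # coxph.control default iter.max
    flagged = flagged, note = note),
    class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> n=%d events=%d loglik=%.2f AIC=%.2f%s\n",
              x$n, x$n_events, x$loglik, x$aic,
              if (isTRUE(x$flagged)) paste0(" [FLAGGED: ", x$note, "]") else ""))
  tb <- x$table
  tb$hr <- signif(tb$hr, 3); tb$ci_lower <- signif(tb$ci_lower, 3)
  tb$ci_upper <- signif(tb$ci_upper, 3); tb$p <- signif(tb$p, 3)
  print(tb, row.names = FALSE)
  invisible(x)
}

fit_cox <- function(records, covariates) {
  check_cohort(records)
  miss <- setdiff(covariates, names(records))
  if (length(miss))
    stop_myelogate(paste("covariates missing from records:",
                         paste(miss, collapse = ", ")), "validation_error")
  if (sum(records$event) < 1L)
    stop_myelogate("Cox regression requires at least one event",
                   "validation_error")
  f <- stats::as.formula(paste(
    "survival::Surv(time_months, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  flagged <- FALSE; note <- NA_character_
  fit <- withCallingHandlers(
    survival::coxph(f, data = records, ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE; note <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  cox_result(fit, covariates, flagged = flagged, note = note)
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit (Efron tie handling) of survival on a single
#' covariate. Degenerate fits (constant covariate, non-convergence,
#' complete separation) are returned flagged, never silently.
#'
#' @param records cohort data frame with `time_months` and `event`.
#' @param covariate name of a numeric, binary, or factor column.
#' @return A `cox_result`: per-covariate hazard ratio, 95% CI, p-value,
#'   log-likelihood, AIC, n, events, convergence/flag status.
#' @export
cox_univariate <- function(records, covariate) {
  v <- records[[covariate]]
  if (!is.null(v) && length(unique(v[!is.na(v)])) < 2L) {
    # constant covariate: HR is undefined; report the degenerate HR = 1
    null_fit <- survival::coxph(
      survival::Surv(time_months, event) ~ 1, data = check_cohort(records))
    res <- structure(list(
      covariates = covariate,
      table = data.frame(covariate = covariate, hr = 1, ci_lower = NA_real_,
                         ci_upper = NA_real_, p = NA_real_,
                         stringsAsFactors = FALSE),
      loglik = null_fit$loglik[length(null_fit$loglik)],
      aic = -2 * null_fit$loglik[length(null_fit$loglik)],
      n = nrow(records), n_events = sum(records$event),
      converged = TRUE, flagged = TRUE,
      note = "covariate is constant; hazard ratio undefined"),
      class = "cox_result")
    return(res)
  }
  fit_cox(records, covariate)
}

#' Multivariate Cox proportional-hazards regression
#'
#' Joint fit of several covariates (typically those retained by
#' [aic_select()]). Emits an events-per-variable warning below 10 events
#' per covariate; requires more observations than covariates.
#'
#' @param records cohort data frame.
#' @param covariates character vector of covariate names.
#' @return A `cox_result`.
#' @export
cox_multivariate <- function(records, covariates) {
  if (!length(covariates))
    stop_myelogate("at least one covariate required", "validation_error")
  if (nrow(records) < length(covariates))
    stop_myelogate("fewer records than covariates", "validation_error")
  n_ev <- sum(records$event)
  if (n_ev < length(covariates))
    stop_myelogate("fewer events than covariates", "validation_error")
  if (n_ev / length(covariates) < 10)
    warning(sprintf("only %.1f events per variable (< 10); estimates may be unstable",
                    n_ev / length(covariates)), call. = FALSE)
  fit_cox(records, covariates)
}

#' AIC-guided covariate selection for the multivariate Cox model
#'
#' Chooses the covariate subset minimizing the AIC of the Cox fit. For up
#' to `exhaustive_limit` candidates every subset (including the null
#' model) is scored; beyond that, backward stepwise elimination is used.
#' The full AIC trace is returned so the selection is auditable.
#' Perfectly collinear candidate pairs are reduced to one member with a
#' warning before the search.
#'
#' @param records cohort data frame.
#' @param candidates character vector of candidate covariate names.
#' @param exhaustive_limit maximum candidate count for exhaustive search.
#' @return list: `selected` (character vector, possibly empty = null
#'   model), `aic` of the winning model, `trace` data frame (model, aic),
#'   `dropped_collinear`.
#' @export
aic_select <- function(records, candidates, exhaustive_limit = 10L) {
  check_cohort(records)
  if (!length(candidates))
    stop_myelogate("no candidate covariates", "validation_error")
  miss <- setdiff(candidates, names(records))
  if (length(miss))
    stop_myelogate(paste("unknown candidates:", paste(miss, collapse = ", ")),
                   "validation_error")
  # drop exact collinear duplicates (keep first of each correlated pair)
  dropped <- character()
  num <- candidates[vapply(candidates, function(cv)
    is.numeric(records[[cv]]) && length(unique(records[[cv]])) > 1L,
    logical(1))]
  if (length(num) > 1L) {
    cm <- suppressWarnings(stats::cor(records[num]))
    for (i in seq_along(num)) for (j in seq_len(i - 1L)) {
      if (isTRUE(abs(cm[i, j]) > 1 - 1e-12) && !(num[i] %in% dropped))
        dropped <- c(dropped, num[i])
    }
    if (length(dropped)) {
      warning("dropping perfectly collinear candidate(s): ",
              paste(dropped, collapse = ", "), call. = FALSE)
      candidates <- setdiff(candidates, dropped)
    }
  }
  score <- function(subset) {
    if (!length(subset)) {
      fit <- survival::coxph(survival::Surv(time_months, event) ~ 1,
                             data = records)
      return(-2 * fit$loglik[length(fit$loglik)])
    }
    tryCatch(fit_cox(records, subset)$aic, error = function(e) Inf)
  }
  trace <- list()
  if (length(candidates) <= exhaustive_limit) {
    subsets <- list(character())
    for (k in seq_along(candidates))
      subsets <- c(subsets, utils::combn(candidates, k, simplify = FALSE))
    aics <- vapply(subsets, score, numeric(1))
    trace <- data.frame(
      model = vapply(subsets, function(s)
        if (length(s)) paste(s, collapse = "+") else "(null)", character(1)),
      aic = aics, stringsAsFactors = FALSE)
    best <- subsets[[which.min(aics)]]
  } else {
    current <- candidates
    best_aic <- score(current)
    trace <- data.frame(model = paste(current, collapse = "+"),
                        aic = best_aic, stringsAsFactors = FALSE)
    repeat {
      if (!length(current)) break
      cand_aics <- vapply(seq_along(current), function(i)
        score(current[-i]), numeric(1))
      i_best <- which.min(cand_aics)
      if (cand_aics[i_best] < best_aic) {
        current <- current[-i_best]
        best_aic <- cand_aics[i_best]
        trace <- rbind(trace, data.frame(
          model = if (length(current)) paste(current, collapse = "+")
                  else "(null)",
          aic = best_aic, stringsAsFactors = FALSE))
      } else break
    }
    best <- current
  }
  list(selected = best, aic = min(trace$aic), trace = trace,
       dropped_collinear = dropped)
}
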