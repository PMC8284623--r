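# Synthetic survival-cohort generator: exponential proportional-hazards
# model in which the hazard depends on membership of the high
# microglia:TAM-ratio group (above the realized cohort median) and on MGMT
# promoter methylation status, with independent exponential censoring.

#' Specification for a simulated survival cohort
#'
#' @param n_patients number of cases (>= 2).
#' @param baseline_hazard baseline event rate, events per month. The default
#'   `log(2)/15` gives a median survival of 15 months in the reference
#'   group, the oft-quoted figure for glioblastoma.
#' @param log_hr_ratio_high log hazard ratio of the high microglia:TAM-ratio
#'   group vs low (negative = protective).
#' @param log_hr_mgmt log hazard ratio of MGMT-methylated vs unmethylated.
#' @param censoring_rate independent exponential censoring rate per month
#'   (0 = no censoring).
#' @param ratio_meanlog,ratio_sdlog log-normal parameters of the per-case
#'   microglia:TAM ratio distribution.
#' @param p_mgmt probability a case is MGMT-methylated.
#' @param p_idh1 probability a case is IDH1-mutant (excluded downstream by
#'   convention, as IDH1-mutant tumors are a biologically distinct entity).
#' @param seed integer RNG seed.
#' @return A validated `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n_patients = 30L,
                            baseline_hazard = log(2) / 15,
                            log_hr_ratio_high = log(0.32),
                            log_hr_mgmt = log(0.23),
                            censoring_rate = 0.01,
                            ratio_meanlog = 0, ratio_sdlog = 1,
                            p_mgmt = 0.4, p_idh1 = 0,
                            seed = 1L) {
  assert_scalar_number(n_patients, "n_patients", lower = 2)
  assert_scalar_number(baseline_hazard, "baseline_hazard", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(censoring_rate, "censoring_rate", lower = 0)
  assert_scalar_number(p_mgmt, "p_mgmt", 0, 1)
  assert_scalar_number(p_idh1, "p_idh1", 0, 1)
  structure(list(n_patients = as.integer(n_patients),
                 baseline_hazard = baseline_hazard,
                 log_hr_ratio_high = log_hr_ratio_high,
                 log_hr_mgmt = log_hr_mgmt,
                 censoring_rate = censoring_rate,
                 ratio_meanlog = ratio_meanlog, ratio_sdlog = ratio_sdlog,
                 p_mgmt = p_mgmt, p_idh1 = p_idh1, seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Simulate a survival cohort with known hazard structure
#'
#' Each case gets a microglia:TAM ratio drawn from the configured
#' log-normal, an MGMT status, and an IDH1 status. The case's hazard is
#' `baseline_hazard * exp(log_hr_ratio_high * I(ratio > median ratio) +
#' log_hr_mgmt * mgmt)`; survival times are exponential with that rate and
#' independently exponentially censored.
#'
#' @param spec a [cohort_sim_spec()].
#' @return data frame (class `cohort`) with columns `case_id`,
#'   `time_months`, `event` (1 = death observed), `ratio`,
#'   `ratio_group_true` (the generating high/low indicator),
#'   `mgmt_methylated`, `idh1_mutant`. Deterministic for a fixed spec.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    ratio <- stats::rlnorm(n, spec$ratio_meanlog, spec$ratio_sdlog)
    high <- as.integer(ratio > stats::median(ratio))
    mgmt <- stats::rbinom(n, 1, spec$p_mgmt)
    idh1 <- stats::rbinom(n, 1, spec$p_idh1)
    rate <- spec$baseline_hazard *
      exp(spec$log_hr_ratio_high * high + spec$log_hr_mgmt * mgmt)
    t_event <- stats::rexp(n, rate)
    t_cens <- if (spec$censoring_rate > 0)
      stats::rexp(n, spec$censoring_rate) else rep(Inf, n)
    out <- data.frame(
      case_id = sprintf("case%03d", seq_len(n)),
      time_months = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      ratio = ratio,
      ratio_group_true = ifelse(high == 1L, "high", "low"),
      mgmt_methylated = mgmt,
      idh1_mutant = idh1,
      stringsAsFactors = FALSE)
    class(out) <- c("cohort", class(out))
    out
  })
}
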