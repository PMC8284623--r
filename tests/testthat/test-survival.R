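cohort_fixture <- function(time, event, ...) {
  extra <- list(...)
  out <- data.frame(case_id = sprintf("c%02d", seq_along(time)),
                    time_months = time, event = event,
                    stringsAsFactors = FALSE)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

test_that("case exclusion drops matching records and logs reasons", {
  rec <- cohort_fixture(c(5, 10, 15), c(1, 1, 0),
                        idh1_mutant = c(0L, 1L, 0L))
  out <- exclude_cases(rec, list(idh1_mutant = 1L))
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "exclusions")$case_id, "c02")
  expect_identical(nrow(exclude_cases(rec, list())), 3L)   # empty rules
  expect_error(exclude_cases(rec, list(nonexistent = 1)),
               class = "config_error")
  expect_warning(exclude_cases(rec, list(idh1_mutant = c(0L, 1L))),
                 "every record")
})

test_that("median split follows the documented tie convention", {
  rec <- cohort_fixture(rep(10, 4), rep(1, 4), m = c(1, 2, 3, 4))
  out <- median_split(rec, "m")
  expect_equal(as.character(out$group_m), c("low", "low", "high", "high"))
  expect_equal(attr(out, "split")$median, 2.5)
  # ties at the exact median go low by default
  rec2 <- cohort_fixture(rep(10, 4), rep(1, 4), m = c(1, 2, 2, 3))
  out2 <- median_split(rec2, "m")
  expect_equal(as.character(out2$group_m), c("low", "low", "low", "high"))
  out2h <- median_split(rec2, "m", ties = "high")
  expect_equal(as.character(out2h$group_m), c("low", "high", "high", "high"))
  # odd n
  rec3 <- cohort_fixture(rep(10, 3), rep(1, 3), m = c(1, 2, 3))
  expect_equal(as.character(median_split(rec3, "m")$group_m),
               c("low", "low", "high"))
  # degenerate: all equal
  rec4 <- cohort_fixture(rep(10, 3), rep(1, 3), m = c(2, 2, 2))
  expect_error(median_split(rec4, "m"), class = "degenerate_split_error")
})

test_that("KM matches the closed form with no censoring", {
  rec <- cohort_fixture(1:4, rep(1L, 4))
  km <- km_estimate(rec)
  expect_equal(km$all$curve$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$all$median, 2)
  # all censored: survival identically 1, median undefined
  recC <- cohort_fixture(1:4, rep(0L, 4))
  kmC <- km_estimate(recC)
  expect_true(all(kmC$all$curve$surv == 1))
  expect_true(is.na(kmC$all$median))
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(4)
  t <- round(rexp(60, 0.1), 3)
  rec <- cohort_fixture(t, rep(1L, 60))
  km <- km_estimate(rec)$all$curve
  emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("KM median approximates ln2/lambda on exponential data", {
  spec <- cohort_sim_spec(n_patients = 5000, baseline_hazard = 0.05,
                          log_hr_ratio_high = 0, log_hr_mgmt = 0,
                          censoring_rate = 0, seed = 12)
  km <- km_estimate(simulate_cohort(spec))
  expect_lt(abs(km$all$median - log(2) / 0.05) / (log(2) / 0.05), 0.05)
})

test_that("log-rank is null on identical groups and valid on one group", {
  rec <- cohort_fixture(c(1:5, 1:5), rep(1L, 10),
                        grp = rep(c("a", "b"), each = 5))
  lr <- logrank_test(rec, "grp")
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  expect_equal(lr$df, 1L)
  rec1 <- cohort_fixture(1:5, rep(1L, 5), grp = rep("a", 5))
  expect_error(logrank_test(rec1, "grp"), "2 groups")
})

test_that("log-rank p agrees with a permutation null on a small fixture", {
  set.seed(7)
  rec <- cohort_fixture(c(rexp(14, 0.2), rexp(14, 0.45)),
                        rbinom(28, 1, 0.9),
                        grp = rep(c("lo", "hi"), each = 14))
  p_chisq <- logrank_test(rec, "grp")$p
  p_perm <- oracle_logrank_perm(rec, "grp", n_perm = 2000)
  expect_lt(abs(p_chisq - p_perm), 0.04)
})

test_that("univariate Cox recovers the generating hazard ratio", {
  spec <- cohort_sim_spec(n_patients = 2000, baseline_hazard = 0.05,
                          log_hr_ratio_high = -1, log_hr_mgmt = 0,
                          censoring_rate = 0, seed = 33)
  co <- simulate_cohort(spec)
  co$high <- as.integer(co$ratio_group_true == "high")
  fit <- cox_univariate(co, "high")
  expect_lt(abs(fit$table$hr - exp(-1)), 0.05)
  expect_true(fit$table$ci_lower < fit$table$hr &
                fit$table$hr < fit$table$ci_upper)
  expect_equal(fit$aic, 2 * 1 - 2 * fit$loglik)
  # duplicating every record leaves the point estimate essentially
  # unchanged (duplication creates ties, so the Efron correction shifts
  # the estimate by a negligible amount rather than zero)
  fit2 <- cox_univariate(rbind(co, transform(co, case_id = paste0(case_id, "b"))),
                         "high")
  expect_equal(fit2$table$hr, fit$table$hr, tolerance = 2e-3)
})

test_that("constant covariates yield a flagged degenerate result", {
  rec <- cohort_fixture(1:6, rep(1L, 6), z = rep(3, 6))
  fit <- cox_univariate(rec, "z")
  expect_true(fit$flagged)
  expect_equal(fit$table$hr, 1)
})

test_that("AIC selection keeps signal, drops noise and collinear twins", {
  spec <- cohort_sim_spec(n_patients = 2000, log_hr_ratio_high = -1.2,
                          log_hr_mgmt = 0, censoring_rate = 0, seed = 44)
  co <- simulate_cohort(spec)
  co$high <- as.integer(co$ratio_group_true == "high")
  set.seed(1); co$noise <- rnorm(nrow(co))
  sel <- aic_select(co, c("high", "noise"))
  expect_true("high" %in% sel$selected)
  expect_equal(nrow(sel$trace), 4)   # null, each single, both
  # single candidate: selected iff better than null
  sel1 <- aic_select(co, "high")
  expect_identical(sel1$selected, "high")
  # perfectly collinear pair collapses with a warning
  co$high2 <- co$high
  expect_warning(sel2 <- aic_select(co, c("high", "high2")), "collinear")
  expect_false("high2" %in% sel2$selected)
})

test_that("multivariate Cox jointly recovers two known log hazard ratios", {
  spec <- cohort_sim_spec(n_patients = 2000, baseline_hazard = 0.05,
                          log_hr_ratio_high = -1.6, log_hr_mgmt = -1.5,
                          censoring_rate = 0, p_mgmt = 0.5, seed = 55)
  co <- simulate_cohort(spec)
  co$high <- as.integer(co$ratio_group_true == "high")
  fit <- cox_multivariate(co, c("high", "mgmt_methylated"))
  hrs <- fit$table$hr[match(c("high", "mgmt_methylated"),
                            fit$table$covariate)]
  expect_lt(abs(hrs[1] - exp(-1.6)), 0.06)
  expect_lt(abs(hrs[2] - exp(-1.5)), 0.06)
  # an all-zero covariate must not move the other estimates
  co$zero <- 0
  fitz <- suppressWarnings(cox_multivariate(co, c("high", "mgmt_methylated",
                                                  "zero")))
  expect_equal(fitz$table$hr[fitz$table$covariate == "high"], hrs[1],
               tolerance = 1e-6)
  expect_error(cox_multivariate(co[1:2, ], c("high", "mgmt_methylated",
                                             "zero")),
               "fewer")
})

test_that("median-split Cox is invariant to monotone metric transforms", {
  spec <- cohort_sim_spec(n_patients = 200, log_hr_ratio_high = -1,
                          censoring_rate = 0.01, seed = 66)
  co <- simulate_cohort(spec)
  r1 <- ratio_survival_analysis(co, metric = "ratio", exclusions = NULL)
  co$ratio <- log(co$ratio)   # monotone transform
  r2 <- ratio_survival_analysis(co, metric = "ratio", exclusions = NULL)
  expect_identical(as.character(r1$records$group_ratio),
                   as.character(r2$records$group_ratio))
  expect_equal(r1$cox_uni$table$hr, r2$cox_uni$table$hr)
})

test_that("events-per-variable warning fires on small cohorts", {
  spec <- cohort_sim_spec(n_patients = 15, censoring_rate = 0, seed = 2)
  co <- simulate_cohort(spec)
  co$high <- as.integer(co$ratio_group_true == "high")
  expect_warning(cox_multivariate(co, c("high", "mgmt_methylated")),
                 "events per variable")
})
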