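cells_df <- function(iba1, p2ry12 = NULL, cd163 = NULL,
                     tissue = "grade_iv", case = "c1") {
  n <- length(iba1)
  tab <- data.frame(case_id = case, tissue_type = tissue, cell_id = seq_len(n),
                    x_px = 0, y_px = 0, area_px = 30L, area_um2 = 7.5,
                    tissue_area_mm2 = 0.1, mean_Iba1 = iba1,
                    stringsAsFactors = FALSE)
  if (!is.null(p2ry12)) tab$mean_P2RY12 <- p2ry12
  if (!is.null(cd163)) tab$mean_CD163 <- cd163
  myelogate:::as_cell_table(tab)
}

test_that("master gate marks cells below the Iba1 region as debris", {
  tab <- cells_df(iba1 = c(1, 2, 3, 4, 5), p2ry12 = rep(0, 5))
  sch <- default_scheme(master_lo = 3)
  calls <- apply_master_gate(tab, sch)
  expect_equal(sum(calls$primary_label == "total"), 3)  # boundary 3 -> upper
  expect_equal(sum(calls$primary_label == "debris"), 2)
  # permissive gate [0, Inf): zero debris
  calls0 <- apply_master_gate(tab, default_scheme(master_lo = 0))
  expect_equal(sum(calls0$primary_label == "debris"), 0)
  # gate above everything: all debris
  calls9 <- apply_master_gate(tab, default_scheme(master_lo = 9))
  expect_equal(sum(calls9$primary_label == "debris"), 5)
  # missing marker column -> schema error
  tab2 <- tab; tab2$mean_Iba1 <- NULL
  expect_error(apply_master_gate(tab2, sch), class = "schema_error")
})

test_that("microglia/TAM split partitions the non-debris cells", {
  tab <- cells_df(iba1 = c(0.5, rep(100, 6)),
                  p2ry12 = c(200, 200, 150, 91, 90, 10, 0))
  calls <- classify_microglia_tam(tab, default_scheme(split_lo = 90))
  expect_equal(calls$primary_label,
               c("debris", "microglia", "microglia", "microglia",
                 "microglia", "tam", "tam"))  # 90 exactly -> upper region
  tot <- table(calls$primary_label)
  expect_equal(sum(tot), nrow(tab))
  # all above the split -> 100% microglia
  hi <- cells_df(iba1 = rep(100, 4), p2ry12 = rep(120, 4))
  expect_true(all(classify_microglia_tam(hi, default_scheme(90))$
                    primary_label == "microglia"))
})

test_that("zero-noise well-separated simulation gates with no errors", {
  tab <- simulate_cell_table(separated_spec(n_mg = 400, n_tam = 400,
                                            seed = 31))
  calls <- classify_microglia_tam(tab, default_scheme(split_lo = 90))
  expect_identical(calls$primary_label, tab$true_label)
})

test_that("misclassification matches analytic Gaussian overlap at 2 SD", {
  # means 2 SD each side of the midpoint threshold
  model <- default_intensity_model(c("Iba1", "P2RY12"))
  model$microglia$P2RY12 <- list(mean = 110, sd = 10)
  model$tam$P2RY12 <- list(mean = 70, sd = 10)
  spec <- image_sim_spec(n_microglia = 3000, n_tam = 3000,
                         marker_panel = c("Iba1", "P2RY12"),
                         intensity_model = model, seed = 41)
  tab <- simulate_cell_table(spec)
  calls <- classify_microglia_tam(tab, default_scheme(split_lo = 90))
  err <- mean(calls$primary_label != tab$true_label)
  p <- pnorm(-2)
  expect_lt(abs(err - p), 3 * sqrt(p * (1 - p) / nrow(tab)))
})

test_that("enlarging the microglia region never decreases microglia count", {
  tab <- simulate_cell_table(separated_spec(n_mg = 300, n_tam = 300,
                                            seed = 51, noise_sd = 0))
  counts <- vapply(c(160, 120, 90, 60, 20), function(lo)
    sum(classify_microglia_tam(tab, default_scheme(split_lo = lo))$
          primary_label == "microglia"), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("gating is a pure function of table and scheme", {
  tab <- simulate_cell_table(separated_spec(n_mg = 50, n_tam = 50, seed = 3))
  sch <- default_scheme()
  expect_identical(classify_microglia_tam(tab, sch),
                   classify_microglia_tam(tab, sch))
})

test_that("control threshold uses the interpolated pooled quantile", {
  ctrl <- cells_df(iba1 = rep(100, 100), cd163 = 1:100)
  th <- derive_control_threshold(ctrl, "CD163", 0.99)
  expect_equal(as.numeric(th), 99.01)
  expect_equal(attr(th, "n_control"), 100L)
  # degenerate constant control
  ctrl2 <- cells_df(iba1 = rep(100, 10), cd163 = rep(7, 10))
  expect_equal(as.numeric(derive_control_threshold(ctrl2, "CD163", 0.5)), 7)
  expect_error(derive_control_threshold(ctrl, "CD163", 1.0), "quantile")
  expect_error(derive_control_threshold(ctrl, "P2RY12", 0.99), "CD14 or CD163")
  expect_error(derive_control_threshold(list(), "CD163", 0.99),
               class = "insufficient_data_error")
})

test_that("high/low split respects the threshold and debris exclusion", {
  tab <- cells_df(iba1 = rep(100, 4), p2ry12 = rep(100, 4),
                  cd163 = c(1, 5, 10, 20))
  expect_equal(classify_high_low(tab, "CD163", 0.5),
               rep("cd_high", 4))   # threshold below all positive values
  expect_equal(classify_high_low(tab, "CD163", 100),
               rep("cd_low", 4))    # threshold above global max
  nd <- c(FALSE, TRUE, TRUE, TRUE)
  out <- classify_high_low(tab, "CD163", 10, non_debris = nd)
  expect_true(is.na(out[1]))
  expect_equal(out[2:4], c("cd_low", "cd_high", "cd_high"))
  expect_error(classify_high_low(tab, "CD14", 1), class = "schema_error")
})

test_that("epilepsy-preset cells stay below the control-derived threshold", {
  ctrl_tabs <- lapply(1:3, function(k)
    simulate_cell_table(image_sim_preset("epilepsy", n_cells = 400,
                                         seed = 100 + k),
                        case_id = paste0("ctrl", k),
                        tissue_type = "epilepsy"))
  th <- derive_control_threshold(ctrl_tabs, "CD163", 0.99)
  test_tab <- simulate_cell_table(image_sim_preset("epilepsy",
                                                   n_cells = 2000,
                                                   seed = 999),
                                  tissue_type = "epilepsy")
  frac_high <- mean(classify_high_low(test_tab, "CD163", th) == "cd_high")
  expect_lte(frac_high, 0.01 + 3 * sqrt(0.01 * 0.99 / 2000))
  # and the epilepsy scene is essentially all microglia
  calls <- classify_microglia_tam(test_tab, default_scheme())
  expect_gt(mean(calls$primary_label == "microglia"), 0.95)
})

test_that("gate_report closes its arithmetic and is additive over cases", {
  tabs <- lapply(1:2, function(k)
    simulate_cell_table(separated_spec(n_mg = 20, n_tam = 10,
                                       seed = 70 + k),
                        case_id = paste0("case", k)))
  sch <- default_scheme()
  reports <- lapply(tabs, function(tb)
    gate_report(classify_microglia_tam(tb, sch), tb))
  pooled <- pool_cases(tabs)
  rep_pooled <- gate_report(classify_microglia_tam(pooled, sch), pooled)
  expect_equal(sum(rep_pooled$microglia),
               sum(vapply(reports, function(r) sum(r$microglia), numeric(1))))
  expect_equal(rep_pooled$microglia + rep_pooled$tam, rep_pooled$total)
  # empty table -> all-zero report
  empty <- tabs[[1]][0, ]
  rep0 <- gate_report(classify_microglia_tam(empty, sch), empty)
  expect_equal(nrow(rep0), 0)
  # coverage mismatch -> integrity error
  expect_error(gate_report(classify_microglia_tam(tabs[[1]], sch),
                           tabs[[2]]), class = "integrity_error")
})

test_that("polygon gates classify by point-in-polygon with boundary inside", {
  poly <- cbind(c(50, 200, 200, 50), c(50, 50, 200, 200))  # P2RY12 x Iba1
  g <- gate("mg_poly", c("P2RY12", "Iba1"), polygon = poly)
  tab <- cells_df(iba1 = c(100, 100, 30, 50), p2ry12 = c(100, 20, 100, 50))
  expect_equal(gate_membership(g, tab), c(TRUE, FALSE, FALSE, TRUE))
  expect_error(gate("bad", c("a", "b"),
                    polygon = cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))),
               "simple")
  expect_error(gate("bad1d", "Iba1", lo = 5, hi = 5), "lo < hi")
})

test_that("suggested split threshold lands between the two populations", {
  tab <- simulate_cell_table(separated_spec(n_mg = 300, n_tam = 300,
                                            seed = 77))
  th <- suggest_split_threshold(tab$mean_P2RY12)
  expect_gt(as.numeric(th), 60)
  expect_lt(as.numeric(th), 120)
  calls <- classify_microglia_tam(
    tab, default_scheme(split_lo = as.numeric(th)))
  expect_identical(calls$primary_label, tab$true_label)
})

test_that("epilepsy gate variants are applied to epilepsy tables only", {
  sch <- gating_scheme(
    gate("master", "Iba1", lo = 1), gate("split", "P2RY12", lo = 90),
    epilepsy_variant = list(split_gate = gate("split_ep", "P2RY12",
                                              lo = 50,
                                              tissue_scope = "epilepsy")))
  tab_t <- cells_df(iba1 = rep(100, 2), p2ry12 = c(70, 95))
  tab_e <- cells_df(iba1 = rep(100, 2), p2ry12 = c(70, 95),
                    tissue = "epilepsy", case = "e1")
  expect_equal(classify_microglia_tam(tab_t, sch)$primary_label,
               c("tam", "microglia"))
  expect_equal(classify_microglia_tam(tab_e, sch)$primary_label,
               c("microglia", "microglia"))
})
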