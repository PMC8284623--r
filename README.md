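# myelogate

Image cytometry of myeloid cells in brain-tumor tissue: delineating
brain-resident **microglia** from invading **tumor-associated macrophages
(TAMs)** in multiplex immunofluorescence images, and relating the per-case
microglia:TAM ratio to patient survival.

Microglia and TAMs are ontogenetically distinct but have long been
conflated in tissue studies because pan-myeloid markers (Iba1) label both.
Single-cell transcriptomics identified microglia-specific markers (P2RY12,
TMEM119) and TAM-enriched markers (CD14, CD163). `myelogate` implements the
full analysis chain that turns marker images into per-patient statistics:

1. **Masking** — binarize each marker channel (fixed / Otsu / quantile
   threshold); the pixelwise union is the *master mask* of all myeloid
   cells.
2. **Object detection** — connected components (4/8-connectivity) of the
   master mask above a minimum area are cells.
3. **Measurement** — per-cell mean intensity of every marker, centroid,
   area; per-image stained-tissue area (mm²) — an FCS-like single-cell
   table.
4. **Gating** — flow-cytometry-style hierarchy: Iba1 master gate (debris
   exclusion), microglial-marker split (microglia = Iba1⁺ P2RY12⁺/TMEM119⁺,
   TAM = Iba1⁺ P2RY12⁻/TMEM119⁻), and a CD14/CD163 high/low split
   calibrated as a quantile (default 0.99) of negative-control (epilepsy)
   staining.
5. **Population metrics** — per-case proportions of total gated cells,
   densities (cells/mm²), microglia:TAM ratio, per-population mean
   intensities, global-expression index; Mann–Whitney / paired-t / two-way
   ANOVA comparisons with a Shapiro–Wilk/F-test assumption gate.
6. **Survival** — median split of any per-case metric into high/low
   cohorts; Kaplan–Meier, log-rank, univariate Cox (Efron ties), AIC-guided
   variable selection, multivariate Cox — e.g. the microglia:TAM ratio
   adjusted for MGMT methylation status, after excluding IDH1-mutant cases.

Because no imaging or clinical data are distributed, the package includes
simulators with analytic ground truth: multiplex images of two cell
populations with configurable intensity models (bimodal microglial marker,
log-normal CD14/CD163 continuum, vessel-associated control TAMs) and
survival cohorts with known exponential proportional-hazards structure.
Every pipeline stage is validated against these plus independent oracles
(exhaustive flood fill, rank-permutation enumeration, closed forms).

## Worked example

```r
library(myelogate)

## a grade-IV-like scene with known ground truth
spec <- image_sim_spec(width_px = 512, height_px = 512, pixel_size_um = 0.5,
                       n_microglia = 60, n_tam = 40,
                       background_level = 20, noise_sd = 4,
                       blur_sigma_px = 1, seed = 42)
sim <- simulate_image(spec, case_id = "GBM01", tissue_type = "grade_iv")
sim$image
#> <multiplex_image> case GBM01 (grade_iv): 512 x 512 px @ 0.5 um/px
#>   markers: Iba1, P2RY12, CD163

cells <- segment_image(sim$image, method = "fixed", param = 40,
                       min_area_px = 10)
nrow(cells)
#> [1] 96
```

96 objects from 100 simulated cells: with a 1 px blur a few close pairs
merge into one master-mask object — the documented touching-cells
limitation (no watershed splitting).

```r
scheme <- gating_scheme(gate("master", "Iba1", lo = 40),
                        gate("mg_split", "P2RY12", lo = 90))
calls <- classify_microglia_tam(cells, scheme)
table(calls$primary_label)
#> microglia       tam
#>        56        40

summarize_case(cells, calls)[, c("total_gated", "prop_microglia",
                                 "density_total", "ratio_mg_tam")]
#>   total_gated prop_microglia density_total ratio_mg_tam
#> 1          96          0.583      1464.844          1.4
```

58% microglia at 1465 myeloid cells/mm² and a microglia:TAM ratio of 1.4.
Downstream, a simulated 120-patient cohort with a protective ratio effect
(true HR 0.32) and an MGMT effect (true HR 0.23):

```r
co <- simulate_cohort(cohort_sim_spec(n_patients = 120, seed = 42))
res <- ratio_survival_analysis(co)   # split -> KM -> log-rank -> Cox -> AIC
signif(res$logrank$p, 3)
#> [1] 5.94e-07
res$cox_uni
#> <cox_result> n=120 events=75 loglik=-290.31 AIC=582.62
#>   covariate    hr ci_lower ci_upper        p
#>  ratio_high 0.303    0.185    0.496 2.06e-06
res$cox_multi
#> <cox_result> n=120 events=75 loglik=-269.79 AIC=543.57
#>        covariate    hr ci_lower ci_upper        p
#>       ratio_high 0.236   0.1400    0.397 5.83e-08
#>  mgmt_methylated 0.150   0.0747    0.300 8.40e-08
```

The high-ratio group's hazard ratio is below 1 both univariately (0.30)
and adjusted for MGMT status (0.24), recovering the generating protective
effect; AIC selection retained both covariates.

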