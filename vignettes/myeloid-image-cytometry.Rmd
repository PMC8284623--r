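---
title: "Image cytometry of microglia and tumor-associated macrophages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image cytometry of microglia and tumor-associated macrophages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Microglia (brain-resident, yolk-sac-derived) and tumor-associated
macrophages (TAMs, peripherally derived) together make up a large share of
the glioblastoma tumor mass, but routine immunohistochemistry has long
conflated them. Single-cell transcriptomics identified markers expressed
only by microglia (P2RY12, TMEM119) and markers enriched in — but not
exclusive to — TAMs (CD14, CD163). `myelogate` implements an image-cytometry
pipeline that uses those markers to classify every myeloid cell in a
multiplex immunofluorescence image, summarize each case's myeloid
composition, and relate the per-case microglia:TAM ratio to patient
survival.

The pipeline has five stages, mirroring how a flow-cytometry analyst would
treat imaging data:

1. **Masking** — each marker channel is binarized; the pixelwise union of
   the per-marker masks is the *master mask* containing all myeloid cells.
2. **Object detection** — connected components of the master mask (8- or
   4-connectivity) larger than `min_area_px` are cells.
3. **Measurement** — per cell, the mean intensity of every marker over the
   cell's pixels, plus centroid and area; per image, the stained tissue
   area in mm².
4. **Gating** — hierarchical thresholds in intensity space: an Iba1 master
   gate removes debris; a microglial-marker split assigns microglia
   (Iba1⁺ P2RY12⁺/TMEM119⁺) vs TAM (Iba1⁺ P2RY12⁻/TMEM119⁻); an optional
   CD14/CD163 threshold derived from negative-control tissue splits cells
   into marker-high and marker-low.
5. **Population metrics and survival** — per-case proportions of total
   gated cells, densities (cells/mm²), the microglia:TAM ratio; then a
   median split of any per-case metric into high/low cohorts feeding
   Kaplan–Meier curves, the log-rank test, and univariate/multivariate Cox
   regression with AIC-guided variable selection.

## The synthetic data model

No imaging or clinical data ship with the package, so a simulator provides
inputs with known ground truth at every stage.

**Images** (`simulate_image()`). Cells are disks with radius drawn from
`cell_radius_px_range`, placed uniformly at random subject to a
non-touching constraint (rims at least 2 px apart) so that connected
components identify single cells; a configurable overlap budget
(`max_overlap_fraction`) exists to exercise the known limitation that
touching cells merge into one object. Each cell's per-marker foreground
intensity is one draw from its population's intensity model; rendering is
`background + foreground`, then Gaussian blur (`blur_sigma_px`), then
additive Gaussian noise. Intensities are arbitrary 16-bit-range floats —
the pipeline only ever uses relative intensities, so no camera model is
needed.

The default intensity model encodes the qualitative structure the gating
relies on:

* **Iba1** bright in both populations (mean 140/160, sd 15) — it is the
  pan-myeloid master channel;
* the **microglial marker** bimodal: mean 150 (sd 10) in microglia vs 30
  (sd 10) in TAMs — two clearly separated populations;
* **CD14/CD163** an overlapping log-normal continuum (meanlog 3.0 vs 3.9,
  sdlog 0.6) — shifted upward in TAMs but not TAM-exclusive, so no split
  exists and a control-derived threshold is required.

Tissue presets (`image_sim_preset()`) encode the control behavior of the
four tissue groups: epilepsy ≈ 97% microglia with near-background CD14/CD163
(residual TAM-like cells placed along a simulated vessel path, emulating
perivascular macrophages), meningioma and low-grade tumors TAM-dominated
(5%/10% microglia), grade IV a mixture (35%). These fractions are declared
defaults chosen to reproduce the qualitative compositions reported for
human tissue; no per-population intensity distributions were available to
fit.

What the simulator deliberately does **not** model: ramified/amoeboid cell
morphology (disks keep ground truth analytic), autofluorescence,
illumination gradients, stitching artifacts, or 3-D structure. Passing
tests on synthetic data therefore demonstrate the correctness of the
*computation* — masking, labeling, measurement, gating arithmetic, survival
statistics — not robustness to real-tissue image quality.

**Cohorts** (`simulate_cohort()`). Survival times are exponential under a
proportional-hazards model: rate `baseline_hazard × exp(β₁·I(ratio >
median) + β₂·MGMT)`, censored by an independent exponential. Defaults:
baseline hazard `log(2)/15` per month (15-month median survival in the
reference group), β₁ = `log(0.32)`, β₂ = `log(0.23)`, censoring 0.01/month,
P(MGMT methylated) = 0.4, log-normal(0, 1) microglia:TAM ratios. The two
log-HRs reproduce the direction and magnitude of the published
glioblastoma finding the package is designed to re-derive; they are
generating values for validation, not estimates of anything.

## Numerical and design choices

* **Thresholding.** Three methods per channel: fixed value, Otsu, and
  intensity quantile (default Otsu; the original workflow's binarization
  method is unpublished, so all three are provided and the resolved
  threshold is always recorded on the mask). Caveat: on sparse-foreground
  frames — a mostly-empty background with a few bright cells — Otsu places
  its threshold inside the background mode and over-segments; use a fixed
  or quantile threshold there.
* **Connectivity and size filter.** Default 8-connectivity and
  `min_area_px = 20` (≈ a 5 µm² soma cross-section at 0.5 µm/px); both are
  arguments. Components are relabeled 1..K in raster order, so labeling is
  deterministic.
* **Touching cells merge.** Each master-mask object *is* a cell by
  definition; no watershed splitting is attempted.
* **Tissue area.** Default = full frame area in mm²; an optional tissue
  mask restricts it when slides contain empty glass. The choice is
  recorded in the cell table.
* **Gate boundaries.** Intervals are closed-left, open-right; a cell
  exactly on a 1-D threshold goes to the upper region. Polygon gates
  (loadable from JSON for parity with hand-drawn contour-plot gates) count
  the boundary as inside.
* **Control threshold.** The CD14/CD163 high/low cut is the 0.99 quantile
  (type-7, linear interpolation) of pooled epilepsy-control cell means. By
  construction ≈1% of control-like cells exceed it, matching the expected
  near-absence of marker-high cells in control tissue.
* **Split-threshold suggestion.** `suggest_split_threshold()` fits a
  two-component unequal-variance Gaussian mixture (EM, deterministic
  quartile-based k-means initialization) and returns the weighted-density
  crossing between the component means. It is an explicit extension — the
  original gates were placed by hand — and is always overridable.
* **Separation convention.** Gating-fidelity tests parameterize difficulty
  by the distance of each population mean from the midpoint threshold in
  within-population SD units: at 6 SDs the per-cell error is Φ(−6) ≈ 10⁻⁹
  (zero errors expected at any realistic cell count); at 2 SDs the error is
  Φ(−2) ≈ 0.023 and the empirical rate is checked against that analytic
  value within binomial tolerance.
* **Zero-TAM ratio.** `microglia_count / tam_count` is `Inf` when a case
  has no TAMs; such cases are excluded from ratio-based statistics. A
  continuity-corrected alternative (+0.5 to both counts) is available.
* **Replicate averaging.** Repeated stainings of one case are collapsed by
  averaging all numeric summary fields *before* any cross-case statistics.
* **Median split.** Values strictly above the cohort median are "high",
  strictly below "low"; ties at the exact median go to "low" by default
  (switchable), and per-group n is always reported.
* **Cox details.** Efron tie handling; AIC selection is exhaustive up to 10
  candidates (including the null model) and backward stepwise beyond, with
  the full AIC trace returned; an events-per-variable warning fires below
  10 events per covariate; degenerate fits (constant covariate,
  non-convergence) are returned flagged rather than silently.
* **Two-way comparisons.** The reported statistic is the
  population × group interaction F under type-II sums of squares
  (unbalanced designs), with Tukey HSD or Sidak-adjusted pairwise
  follow-ups; the Shapiro–Wilk/F-test gate records which route (parametric
  vs nonparametric) the assumptions support.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
connected components against exhaustive min-label propagation on all 512
3×3 masks (both connectivities) and against `EBImage::bwlabel`
(4-connectivity); Mann–Whitney against full rank-permutation enumeration
for all group sizes ≤ 5; per-object means against direct pixel sums on
hand-built fixtures; Kaplan–Meier against the empirical survival function
(exact, no censoring) and the exponential closed form ln 2/λ; the log-rank
p against a 2000-permutation null; Cox estimates against the generating
log-HRs of simulated cohorts, including CI coverage across HR ∈
{0.2, 0.5, 1, 2}.

End-to-end runs use 20 images of 1024×1024 px at 0.5 µm/px with zero
noise/blur (exact count and density recovery), 6000-cell gating
experiments, 500 null replicates at n = 200 for log-rank size, and 100
replicates at n = 300 per condition for Cox recovery and for the
directional reproduction of the protective-ratio finding (high-ratio HR <
1 both univariately and MGMT-adjusted). These sizes put Monte-Carlo error
comfortably inside the assertion tolerances while the whole suite runs in
well under a minute of compute.

## Known limitations

* Disk-shaped cells cannot expose morphology-dependent segmentation errors
  (ramified processes, overlapping arbors).
* Gates are user-supplied or helper-suggested; the original hand-drawn
  gate coordinates are unpublished and no attempt is made to reconstruct
  them.
* Published hazard ratios from tissue cohorts cannot be reproduced without
  the underlying patient data; the survival machinery is validated by
  parameter recovery on simulated cohorts and by direction, not by
  matching published values.
* No spectral unmixing/compensation: channels are assumed unmixed single
  stains.
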