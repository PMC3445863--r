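# sspconcord

Consistency analysis for breast-cancer **intrinsic molecular subtypes**
(luminal A, luminal B, normal breast-like, HER2-enriched, basal-like)
assigned by nearest-centroid **single-sample predictors (SSPs)**.

Several published intrinsic gene lists (Sørlie ~500, Hu 306, PAM50) each
come with subtype centroids, and a new tumour is typed by correlating its
expression profile with the five centroids. Different gene lists — and
different adjustments for systemic microarray bias between the tumour
cohort and the centroids' training cohort — can assign the *same* tumour
to *different* subtypes. `sspconcord` is for analysts who want to quantify
that disagreement on their own cohorts: it implements the whole pipeline
(classification under several bias-adjustment regimes, chance-corrected
agreement, clinical association, survival comparison) plus a synthetic
cohort generator so every stage is testable without any data download.

## The statistics at the core

**Single-sample prediction.** A sample with expression vector `x` over the
signature's gene panel gets Spearman rank correlations
`rho_k = cor(rank(x), rank(c_k))` against the five subtype centroids
`c_1..c_5` (each centroid is the per-gene mean of labelled training
samples). The call is `argmax_k rho_k`, or **Unclassified** when all five
`rho_k < 0.1`; ties are broken deterministically in the fixed label order
and flagged.

**Bias adjustment.** Two regimes besides "none":

* *gene mean-centring* — subtract each gene's cohort mean;
* *distance-weighted discrimination (DWD)* — find the unit direction `w`
  and intercept `b` minimising `sum_i 1/r_i + C sum_i xi_i` subject to
  `r_i = y_i (w.x_i + b) + xi_i > 0`, `xi_i >= 0`, `||w|| <= 1` (batches
  coded `y_i = ±1`), then translate each batch along `w` so both batch
  mean projections become 0. The default penalty is the scale-free
  `C = 100 / median(cross-batch distance)^2`.

Cohorts from two sites are pooled with **quantile normalization** (tied
values receive the mean reference value of the ranks they occupy).

**Agreement.** Pairwise call sets are cross-tabulated (Unclassified kept
as a sixth category by default, or dropped) and summarised by unweighted
Cohen's kappa `(po - pe) / (1 - pe)` with the Fleiss–Cohen–Everitt
large-sample standard error and a `±1.96 se` 95% CI.

**Clinical & survival.** Subtype-by-feature contingency tables (ER, HER2,
grade, nodal status, lymphovascular invasion), the conventional IHC
surrogate (ER+ → luminal-like; ER−/HER2+ → HER2-like; ER−/HER2− →
triple-negative-like), Kaplan–Meier curves and the log-rank test
(via the `survival` package).

## Worked example

```r
library(sspconcord)

cfg  <- sim_config(seed = 42)           # 169 samples, 2 sites, 50 genes
cen  <- simulate_centroids(cfg)
coh  <- simulate_cohort(cfg, cen)

calls_raw <- classify_cohort(coh$matrix, cen)
subtype_distribution(calls_raw)
#>         LumA         LumB       Normal        Her2E        Basal Unclassified
#>           58           32            8           30           41            0

model <- fit_dwd(coh$matrix, coh$batches)
model
#> DWD model over 50 genes; cost = 0.6433
#> batch mean projections: site1 = 0.8181, site2 = 7.1562
#> objective: 52.3149

calls_dwd <- classify_cohort(dwd_adjust(coh$matrix, model), cen)
agreement(calls_raw, calls_dwd)
#> Cohen's kappa (unweighted): 1.0000  se 0.0000  95% CI 1.0000-1.0000  (n = 169)

sv  <- simulate_survival(coh$labels, cfg)
res <- survival_by_subtype(calls_raw, sv)
round(res$logrank$statistic, 3)   # 6.236 on 4 df, p = 0.182
```

Reading: the generator puts a gene-wise additive shift on the site-2
samples; DWD estimates that shift direction from the batch labels and
removes it. At the default shift size the SSP is robust enough that raw
and DWD-adjusted calls agree perfectly (kappa 1.0) — the five subtype
distribution counts are exactly the simulated truth. The log-rank test
across the five called subtypes does not reach significance at this
cohort size, matching what its power properties predict (see the
vignette).

The full orchestration (`run_full()`) runs every signature × adjustment
cell, all pairwise kappas, the consistent-sample clinical tables and the
survival comparison from one config list, and writes per-cell call TSVs
plus a deterministic `report.json`:

```r
report <- run_full(list(
  simulation  = sim_config(seed = 1),
  signatures  = list(sim = list(centroids = cen)),
  adjustments = c("none", "center", "dwd"),
  simulate_survival = TRUE
), out_dir = "results/run1")
```

## Layout

```
R/                  implementation (io, preprocess, dwd, subtype,
                    agreement, clinical, survival, simulate, pipeline)
tests/testthat/     unit + property + acceptance suites
scripts/acceptance.R
inst/extdata/       per-site clinical demographic fixtures (synthetic
                    joint assignment matching published marginal counts)
vignettes/          methods vignette (model, parameters, design choices)
```
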