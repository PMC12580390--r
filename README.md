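# tmespatial

Spatial CAF–TAEC metrics and response statistics for multiplex
immunofluorescence cell tables.

## The problem

In non-small cell lung cancer, squamous tumors respond to neoadjuvant
chemoimmunotherapy (NAIC) more often than adenocarcinomas, and the baseline
tumor microenvironment may explain part of the difference. Cancer-associated
fibroblasts (CAFs, gated aSMA⁺/CK⁻) support angiogenesis through interaction
with tumor-associated endothelial cells (TAECs, CD31⁺/CK⁻); if that
interaction is distance-limited, *how far* CAFs sit from the vasculature in
a pre-treatment biopsy is a candidate predictor of major pathological
response (MPR, ≤10% viable tumor after treatment).

`tmespatial` is for analysts working with inForm-style per-cell exports from
tissue-microarray (TMA) cores: one CSV row per segmented cell with centroid
coordinates (μm) and binary marker positivity. It implements the full chain
from gating to inference:

* **Phenotype gating** — rule-based (required-positive / required-negative
  markers), priority-ordered, with conflict auditing
  (`assign_phenotypes()`).
* **Spatial metrics** per core and per patient (`core_metrics()`,
  `patient_metrics()`):
  * density per 1000 cells: `1000 · n_phenotype / n_cells`;
  * mean nearest-neighbor distance
    `NND = (1/n_CAF) Σᵢ min_j ‖CAFᵢ − TAECⱼ‖` (μm);
  * proximity(r): `#{ i : min_j ‖CAFᵢ − TAECⱼ‖ ≤ r }`, r = 30 μm by
    default.
* **Cohort statistics** — Yates χ² / Fisher dispatch on response tables,
  exact and asymptotic Mann–Whitney, median (Q1, Q3) summaries, dichotomized
  univariate odds ratios with Wald CIs, and ROC with Youden-optimal cutoff
  where the trapezoidal AUC is cross-checked against the concordance
  identity `AUC = (concordant + 0.5·tied)/(n₊·n₋)` at run time.
* **A seeded synthetic cohort generator** — clustered vessel-like TAECs and
  CAFs with a tunable coupling strength κ (fraction of CAFs displaced from a
  random TAEC by a Gaussian offset), differing by response group, so that
  every stage is testable without patient data.

See `vignettes/spatial-tme-methods.Rmd` for the statistical conventions and
the generative model, and `analysis/01…04_*.R` for the narrative workflow
(simulate → metrics → group comparisons → OR/ROC) writing its tables under
`results/`.

## Worked example

Simulate an 11-patient squamous NAIC scaffold (7 MPR, 4 NMPR) in which
responders have weaker CAF–TAEC coupling, then compare groups and evaluate
the distance metric as an MPR predictor:

```r
library(tmespatial)

cfg <- cohort_sim_config(
  groups = tibble::tibble(arm = "NAIC", histology = "SCC",
                          n = c(7, 4), p_mpr = c(1, 0),
                          p_orr = 0.6, p_pcr = 0.2),
  cores_per_patient = 1,
  core_template = core_sim_config(seed = 0L),   # 1 mm² core, 2000 cells
  seed = 7
)
sim     <- simulate_cohort(cfg)
tables  <- lapply(sim$tables, assign_phenotypes)
metrics <- dplyr::inner_join(cohort_metrics(tables), sim$clinical,
                             by = "patient_id")
metrics$response <- ifelse(metrics$MPR, "MPR", "NMPR")

compare_groups(metrics,
               c("density_CAF", "density_TAEC", "mean_nnd_um",
                 "proximity_per1000"),
               "response")
#>           variable                  MPR                 NMPR n1 n2   method       p
#>        density_CAF 450.5 (441.5, 453.5) 460.0 (457.1, 461.2)  7  4 mw_exact 0.23030
#>       density_TAEC 145.5 (141.0, 158.5) 147.8 (142.5, 153.2)  7  4 mw_exact 0.92727
#>        mean_nnd_um    37.9 (37.1, 40.3)    20.8 (19.9, 23.5)  7  4 mw_exact 0.00606
#>  proximity_per1000 249.0 (224.8, 253.5) 382.2 (356.0, 395.1)  7  4 mw_exact 0.00606

roc_curve(metrics$mean_nnd_um, metrics$MPR)
#> <roc_result> AUC = 1 (7 positive, 4 negative)
#>   Youden-optimal threshold 30.12: sensitivity 1, specificity 1
```

Read it as a clinical table: CAF and TAEC *abundance* do not separate the
groups (densities per 1000 cells, exact Mann–Whitney p > 0.2), but the
*spatial arrangement* does — responders' CAFs sit almost twice as far from
the nearest endothelial cell (median 37.9 vs 20.8 μm, p = 0.006), fewer of
them have a TAEC within 30 μm, and the distance alone separates responders
from non-responders perfectly at a ~30 μm cutoff in this simulated cohort
(at the generator's default effect size, which is stronger than a real
cohort would show).

Real data enter the same way via `parse_cell_table("cells.csv")` (column
names configurable through `default_schema()`), or end to end through
`run_pipeline(run_config(cells_csv = ..., clinical_csv = ...,
out_dir = ...))`, which writes the complete report bundle plus a manifest
with warnings and exclusions.

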