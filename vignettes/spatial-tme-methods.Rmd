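---
title: "Spatial CAF-TAEC analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial CAF-TAEC analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmespatial)
```

## The question and the quantities

Cancer-associated fibroblasts (CAFs) support tumor angiogenesis through
paracrine interaction with tumor-associated endothelial cells (TAECs). If
that interaction is distance-limited, the spatial arrangement of the two
populations in a baseline biopsy — not just their abundance — may carry
information about how a tumor will respond to neoadjuvant therapy. This
package quantifies that arrangement in per-cell multiplex immunofluorescence
(mIF) exports from tissue-microarray (TMA) cores and links it to pathological
response.

Cells are gated operationally: a CAF is aSMA+/CK−, a TAEC is CD31+/CK−
(CK marks epithelium; every row of an export is a DAPI-nucleated cell, so no
DAPI column is carried). Three per-core quantities follow:

* **Density per 1000 cells** — `1000 * n_phenotype / n_cells`. PD-L1 and
  PD-1 "expression" use the same formula on marker-positive cells.
* **Mean nearest-neighbor distance (NND)** — the mean over CAFs of the
  Euclidean distance (μm) to the closest TAEC.
* **Proximity(r)** — the number of CAFs with at least one TAEC within
  radius r; r defaults to 30 μm, a physiological bound on direct or
  juxtacrine cell–cell interaction. The boundary is inclusive: a TAEC at
  exactly 30.0 μm counts. We read "within a 30 μm radius" as a closed disc;
  the choice is visible only on a measure-zero set but is documented and
  tested so results are bit-reproducible.

The inference layer mirrors how such cohorts are analyzed: χ²/Fisher tests on
response-rate tables, Mann–Whitney comparisons of the metrics between
responder groups, median (Q1, Q3) summaries, dichotomized univariate odds
ratios, and ROC curves with Youden-optimal operating points. All tests are
two-sided at α = 0.05 with no multiple-testing correction (the number of
tests run is visible in every report table, so a reader can apply their own).

## Statistical conventions and why

**Test dispatch for 2×2 response tables.** The Yates-corrected χ² is the
default; Fisher's exact test is used when any expected count falls below 5
(`dispatch_2x2_test()`). This is the classical rule, and it is the unique
dispatch consistent with the full set of published p-values this package
reproduces in its acceptance checks (a plain Pearson χ² reproduces none of
them). χ² and Fisher go through the standard `stats` implementations, whose
formulas (the `min(0.5, |O−E|)` Yates floor; the two-sided Fisher rule of
summing hypergeometric point probabilities ≤ the observed one with 1e−7
relative tolerance) are exactly the documented contracts; both are verified
against independent enumeration oracles in the test suite.

**Mann–Whitney.** `mann_whitney()` is authored in the package because the
required behavior is not available as one call: exact mode must handle ties
(full enumeration of the `choose(n1+n2, n1)` group assignments, supported to
n1+n2 ≤ 12; the tie-free branch uses the standard U-distribution counting
recursion), and asymptotic mode must use the midrank tie-corrected normal
approximation *without* continuity correction — the convention under which a
7-vs-4 comparison with U = 3 yields p = 0.038, matching how such tables are
reported. `auto` picks exact for n1+n2 ≤ 12, else asymptotic. Two constant
identical samples are degenerate and return p = 1 with a warning rather than
NaN.

**Quartiles.** `median_iqr()` defaults to linear interpolation (type 7);
the SPSS HAVERAGE convention (type 6) is selectable because clinical tables
are often produced under it. The choice changes Q1/Q3 by fractions of an
observation spacing and never affects any test.

**Odds ratios.** "Univariate regression" on a binary predictor and binary
outcome is algebraically the 2×2 cross-product OR, which is what
`univariate_or()` computes, with a Wald CI and p. With any zero cell the
Haldane–Anscombe +0.5 correction is applied to all four cells and flagged in
the output rather than silently. Predictors are dichotomized at the sample
median with ties going to "high" (`dichotomize()`); an all-equal predictor
is an error, not an arbitrary split.

**ROC.** `roc_curve()` computes the empirical curve over all distinct
thresholds (positive when score ≥ threshold). The trapezoidal AUC is
cross-checked at run time against the concordance identity
AUC = (concordant + 0.5·tied) / (n₊·n₋); a mismatch aborts, because it can
only mean an implementation defect. Orientation is auto-chosen so AUC ≥ 0.5
and the flip is recorded — with 7-vs-4 groups a "wrong-direction" marker is
otherwise easy to over-read. Youden ties are broken toward higher
specificity, the convention that favors rule-in cutoffs.

## Spatial computation

Nearest-neighbor queries run on a uniform grid index (`method = "grid"`):
targets are bucketed at cell size `span / sqrt(n_target)` and each query
scans outward ring by ring, stopping when no unvisited ring can contain a
closer point. The exhaustive all-pairs path (`method = "brute"`) is retained
and the two are required to agree *exactly* — not within tolerance — on
randomized instances in the test suite; both paths use the same arithmetic,
so equality is achievable and any deviation is a bug.

No edge correction is applied: a CAF near the core boundary keeps its
observed nearest TAEC. Border corrections (reduced-sample, Kaplan–Meier
style) would change the estimand away from what imaging platforms report;
consistency with the upstream convention matters more here than unbiasedness
under a stationarity assumption that TMA cores do not satisfy anyway.

Undefined metrics are explicit. A core with no CAFs or no TAECs has no NND
(`NA` with a `reason` attribute) and, in the per-core metric table, no
proximity value — reporting 0 would fake extreme isolation or extreme
proximity. The raw `proximity_count()` operation itself returns 0 when no
target exists (a count of CAFs-with-a-near-TAEC is genuinely zero then); the
metric-table `NA` is the analysis-level decision, and the two layers are
documented separately on purpose. Patient-level aggregation (default:
unweighted mean over cores with defined values) records how many cores
contributed to each metric; a patient with no defined core is excluded from
that comparison with a logged warning rather than imputed.

Cores are aggregated to patients by unweighted mean by default because cores
are designed to be equal-sized sampling units; `cell_weighted` (weights:
total cells for densities, CAF count for NND/proximity) and `pooled` are
selectable. The upstream convention for core-to-patient pooling is not
standardized across platforms, so the method tag is carried in every output
row. For `pooled`, cores are laid side by side with a 10 mm gap before the
union point set is formed: a literal union of per-core coordinate frames
would pair cells from different pieces of tissue.

Distances are computed on centroids in μm as given; any pixel-to-μm
conversion belongs to the exporter.

## What the synthetic cohort emulates

`simulate_core()` draws one TMA core: multinomial cell identities
(defaults: 45% CAF, 15% TAEC, 30% tumor, 10% other — matching observed
densities of ~450 and ~150 per 1000), TAECs as a Thomas cluster process
(60 parent "vessel profiles" per mm², cluster sd 20 μm — a microvessel
density in the range reported for NSCLC), and CAFs of which a fraction κ
is *coupled*: each coupled CAF picks a uniformly random TAEC and is displaced
from it by an isotropic Gaussian of scale σ_couple = 15 μm, with
out-of-bounds draws rejected and redrawn. Under these defaults, sweeping κ
from 0 to 1 moves the mean CAF→TAEC NND from ≈50 μm down to ≈13 μm, spanning
the 17–35 μm range observed in real cores; the coupling mechanism itself is
a modeling choice — only the summary statistics it produces are constrained
by data.

`simulate_cohort()` layers patients on top: group sizes and MPR/ORR/pCR
rates from a configurable table (defaults reproduce the 104-patient scaffold:
22/13 NAIC and 24/45 NAC patients by histology), κ drawn per response group
(responders Beta(2,6), mean 0.25; non-responders Beta(6,2), mean 0.75 —
responders' CAFs sit farther from the vasculature). pCR is nested inside MPR
via a single uniform draw, which respects the pathology definitions (pCR ⊂
MPR) and is valid because every configured pCR rate is below the MPR rate.
ORR is drawn independently — RECIST response and pathological response are
distinct measurements. Every per-core seed derives from the master seed by a
fixed counter scheme (`seed + 7919 * core_index mod 2³¹−1`), so any core can
be regenerated alone.

What the generator does **not** emulate: tubular vessel morphology (clusters
are isotropic), cell shapes and sizes (points only), spatial covariation of
marker intensity, batch effects, segmentation errors other than i.i.d.
marker flips, and within-patient core heterogeneity beyond independent
redraws. Tests passing on synthetic cohorts therefore validate the
*computational chain* — gating, metrics, tests, ROC — and the statistical
calibration of that chain; they are not evidence about real-tissue effect
sizes.

`closed_form_checks()` supplies the analytic oracle used throughout the
tests: for a homogeneous Poisson target of intensity λ the expected NND is
`1/(2√λ)` and the proximity probability at radius r is `1 − exp(−λπr²)`.
Finite cores fall slightly short of these infinite-window values, so the
Monte-Carlo checks evaluate interior sources (60 μm margin) and compare
replicate means within 3 empirical standard errors — empirical across
replicates because per-source distances sharing one target realization are
positively correlated and a binomial SE would overstate precision.

## Problem sizes used in validation

The test suite and the acceptance script run the full chain on cohorts of
7 + 4 patients with one 300-cell 0.6 × 0.6 mm core each: 500 replicates for
the null-calibration check (identical κ distributions in both groups;
exact Mann–Whitney at these sizes has rejection rate 14/330 ≈ 0.042 by
discreteness, well inside the 3-SE band around 0.05) and 100–150 replicates
for direction recovery at the default effect size (Beta(2,6) vs Beta(6,2)).
The demonstration workflow under `analysis/` simulates the 36-patient mIF
sub-cohort at full size (2000-cell cores). These sizes are the package's
validation design; all scale linearly if a user wants more.

## Known limitations

* The proximity counts printed in published per-patient tables are of order
  1–5, far below raw per-core CAF counts; the normalization behind them is
  not stated, so this package emits both the raw definitional count and a
  per-1000-cells variant and does not attempt to match those magnitudes.
* Patient-level odds-ratio CIs depend on the (unpublished) patient-level
  2×2 split; the Wald CI here is a method implementation, not a value
  reproduction.
* Exact Mann–Whitney with ties is enumeration-bound (n1+n2 ≤ 12); larger
  tied samples fall back to the tie-corrected asymptotic form with a
  warning.
* Multi-phenotype cells (e.g. aSMA+/CD31+/CK−) are resolved by configurable
  rule priority, CAF first by default, and the conflict count is reported;
  how upstream vendor software resolves them is undocumented, so no attempt
  is made to guess it.
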