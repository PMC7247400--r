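---
title: "Joint dose-time modelling of dynamic dose-responsive genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint dose-time modelling of dynamic dose-responsive genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddrmap)
```

## The model

`ddrmap` treats the per-gene log2 fold-change (LFC) of a dose × time
toxicogenomic design as a smooth surface over the joint dose-time plane.
Both covariates are min-max normalized to [0, 1] before fitting; dose is
log10-transformed first by default (`log10_dose = TRUE`) because tested
doses are usually log-spaced (e.g. 30/100/300 mg/kg), which makes the
normalized dose grid symmetric around the middle dose and keeps the cubic
terms numerically well conditioned. All reported doses, times and fronts are
mapped back to original units.

Four nested linear models are fitted per gene by least squares: a constant,
and full first-, second- and third-order polynomials in dose and time (3, 6
and 10 terms). Each polynomial is tested against the constant model with the
nested-model F statistic

F = ((RSS_r − RSS_f) / (df_r − df_f)) / (RSS_f / df_f),

and the gene's selected model is the order with the smallest test p-value;
p-values are compared on the log scale, so orders remain distinguishable
even when all of them are far below double precision, and the reported value
is floored at 1e-300. Genes whose selected p-value fails a
Benjamini–Hochberg gate across genes (default α = 0.01 on the adjusted
p-value) are flagged non-responsive. Adjusting across genes (rather than
across the three orders within a gene) is the transcriptome-screening
convention; a sequential-step variant (`selection = "sequential"`) tests
each order against its predecessor instead.

Two assumptions matter. First, all pair-samples (every treated × control
pairwise LFC within a dose-time cell) are treated as equally weighted,
independent observations, although pairs sharing a control replicate are in
fact positively correlated; residual degrees of freedom are therefore
somewhat optimistic on real pairwise designs. Second, with only three dose
levels the pure-dose cubic basis {1, D, D², D³} is rank-deficient by one on
the observed dose values. The fits use a pivoted QR, so one pure-dose column
is aliased (coefficient `NA`, treated as zero in prediction) and residual
degrees of freedom follow the achieved rank — the behaviour of `lm` —
rather than raising an error; fitted surfaces and tests are unaffected
because the fitted values are unique.

## From surface to responsive area

The selected surface is evaluated exactly (no resampling) on a
`resolution × resolution` grid (default 50) spanning the tested ranges,
linear in normalized coordinates, with rows = time and columns = dose. The
gradient field is the analytic derivative of the polynomial, evaluated at
the grid points; a central finite-difference mode (`gradient = "finite"`)
exists purely as a cross-check, and the two agree to O(h²).

A grid point is *active* when |LFC| ≥ log2(1 + θ) with θ = 0.10 by default:
the threshold is read on the fold-change scale, i.e. a 10 % change relative
to controls, the customary default of benchmark-dose transcriptomics. (A
literal cut of 1.1 on the log2 scale would correspond to a 2.14-fold change,
inconsistent with a 10 % threshold; `threshold_scale = "lfc"` restores the
raw-scale reading for users who want it.) Active points are segmented by the
sign of the dose gradient into 8-connected components; points with
|∂LFC/∂D| < `grad_tol` (default 1e-9) count as non-monotone and join no
component. Eight-connectivity is the standard raster-morphology choice and
avoids splitting thin diagonal regions.

Components that never reach the highest-dose column disqualify — a gene
whose response does not persist to the highest tested dose is not considered
dose-responsive. Among the rest, the winner maximizes the region weight
r = n_p + n_tp-md − m_d. We interpret m_d as the 1-based grid-column index
of the region's minimum dose, so all three summands are point counts of
comparable magnitude; mixing a mg/kg dose into the sum would make the weight
depend on the dose units. Ties break by larger n_p, then smaller m_d. The
winning region is then audited row by row: any time row that is still active
outside the region with the opposite dose-gradient sign is removed, and the
survivor must remain connected and still reach the highest dose, otherwise
the gene is dropped.

The region border is traced with Moore-neighbour tracing (Jacob's stopping
criterion). Every traced point is a region point adjacent to background or
the grid edge. One known property of Moore tracing: at inner corners whose
only background contact is diagonal, the trace may cut the diagonal and skip
that pixel, so the trace is a subset of (and on convex regions equal to) the
set of all boundary-criterion pixels; the labelling strategies operate on
the traced border. Per time row, the dose-responsive front is the region's
smallest dose and the IC50 front the smallest dose at which |LFC| reaches
half of that row's maximum within the region.

## POD labels and the dose/time influence score

The map is partitioned into equal thirds per axis (grid columns 1–17 /
18–33 / 34–50 at resolution 50; cutpoints `round(res/3)` and
`round(2*res/3)`), labelled Sensitive/Intermediate/Resilient in dose and
Early/Middle/Late in time. Four strategies assign the POD:

* **most_left** (default): dose class of the region's lowest active dose,
  then the earliest active time within that dose band. One label.
* **presence**: all cells holding at least one border point.
* **cumulative**: cells ranked by border share; smallest prefix reaching X %
  (default X = 80). At X = 100 it coincides with presence by construction.
* **mix**: per-cell equal-weight mean of proximity to the Sensitive-Early
  corner (1 − normalized Chebyshev distance), DDRA coverage fraction and
  border share; argmax, ties towards more sensitive then earlier cells. The
  equal weights are a declared choice (`mix_weights`); no reference weights
  exist, so they are exposed in the configuration.

The relative influence of dose and time comes from the gradient field over
the region. Every point contributes an angle (counterclockwise from the
positive dose axis, in normalized covariate units — the unit choice changes
dominance and is deliberately explicit) and a magnitude. The time-dose
response score is, by default, the direction of the magnitude-weighted mean
gradient vector; the plain magnitude-weighted arithmetic mean of angles
(`td_method = "literal"`) is identical away from the 0°/360° wrap but
discontinuous at it (two angles of 350° and 10° average to 180° instead of
0°), which is why the vector form is the default. Quadrants follow the
half-open intervals (0, 90], (90, 180], (180, 270], (270, 360] and give the
signs (quadrant 1: d+, t+; 2: d−, t+; 3: d−, t−; 4: d+, t−). Each quadrant
splits into three 30° sectors: within 30° of the dose axis the dose
dominates (capital D), within 30° of the time axis the time dominates
(capital T), the middle band means comparable effects (both capitals), and
exact 30°/60° boundaries fall in the equal band. A pure positive dose effect
sits exactly on the quadrant-1/4 boundary (0° ≡ 360°); it is resolved to
quadrant 1 with label `D+t+`, since the time sign is vacuous there.

## The synthetic generator

`simulate_experiment()` emulates the reference in vivo design: 3 dose
levels (30/100/300), 4 time points (3/6/9/24 h), 3 treated and 3 control
replicates per cell, hence 9 pairwise LFCs per cell and 108 pair-samples in
total. Each gene is a known surface — the three fitted polynomial families
plus `plateau` (dose-saturating) and `adaptive` (dose response decaying in
time), which lie outside the fitted family and exercise misspecification —
with i.i.d. Gaussian noise on every pair-sample (default σ = 0.05 log2
units, a typical residual scale for averaged microarray LFCs). The preset
coefficient sets (`preset_spec()`) peak around one log2 unit, the size of a
clearly responsive gene. The generator does **not** model the correlation
induced by shared control animals, probe-level effects, batch structure, or
heavy-tailed noise; passing tests on this generator therefore demonstrate
correctness of the algorithmic pipeline under its stated assumptions, not
robustness to those real-data features.

## Numerical choices and problem sizes

* Activity threshold θ > 0 (fraction; default 0.10), gate α = 0.01,
  resolution 50, cumulative X = 80 are all in `ddr_config()`.
* p-values floored at 1e-300; order comparison on log p.
* Zero-gradient tolerance 1e-9 (normalized LFC units per axis unit) for
  monotonicity; gradient magnitudes below 1e-12 are excluded from the
  time-dose score, and an all-zero field is an error surfaced as a
  `degenerate_gradient` drop.
* Degenerate inputs are rejected at load: non-finite LFCs, duplicate or
  missing gene ids, unannotated columns.
* Determinism: a simulation seed fixes the LFC matrix bit-for-bit, and the
  pipeline is deterministic given its inputs, so rerunning with the same
  seed and configuration reproduces the results table byte for byte.

The test suite sizes simulations to what the properties need: 50 random
instances for the least-squares/F-test oracle comparisons, 200 genes per
family for order-recovery operating characteristics, 500-gene batches for
the threshold sweep, and a 2,000-gene batch for the end-to-end determinism
check — sizes chosen so each estimate is stable while the whole suite stays
desk-scale on a single CPU.

## Limitations

Only polynomial families are fitted (they generalize naturally to two
covariates; saturating families like Hill or logistic do not, and genuinely
saturating responses will be approximated, usually by order 2 or 3). One
region is reported per gene — a gene with two opposite-sign responsive
areas yields only the higher-weight one, with the other removed by the row
audit. The enrichment stage is a plain one-sided hypergeometric
overrepresentation test against user-supplied GMT collections with BH
correction (significance at adjusted p < 0.05) over the universe of genes
that entered fitting; no pathway-database retrieval is performed.
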