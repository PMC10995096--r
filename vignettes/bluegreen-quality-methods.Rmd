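---
title: "Methods: composite blue-green landscape quality and GA-BP prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite blue-green landscape quality and GA-BP prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lqci)
```

# The problem

Urban blue-green space — the interconnected system of water bodies and
vegetated areas — is assessed here through a composite quality index built
from yearly socio-economic, ecological and landscape-pattern indicators,
and through a small neural network that predicts that index from 17 raw
indicator columns. The package implements the full chain: class-level
landscape pattern metrics from categorical rasters, AHP-based indicator
weighting, the composite index with ordinal quality levels, plain and
GA-initialized backpropagation training, and error/cross-validation
reporting. The packaged case study covers one urban district over the
eight years 2015–2022; its printed tables ship as CSV fixtures
(`loadFixture()`).

# Landscape pattern metrics

`classMetrics()` computes the six class-level metrics (NP, PD, AREA_MN,
LPI, LSI, AI) with the standard raster definitions used by the common
landscape-ecology tools:

* patches are maximal connected components, 8-neighbor by default
  (configurable to 4);
* PD is patches per km² of landscape (numerically identical to patches
  per 100 ha);
* AREA_MN is the mean patch area in hectares — the fixture series prints
  its area column without units and with values spanning three orders of
  magnitude, so no fixture value is treated as a numeric target for this
  module;
* LSI is `0.25 E / sqrt(A)` with the class edge length `E` counted in
  cell edges *including* the landscape boundary, so a single square patch
  scores exactly 1;
* AI is `100 g / g_max`, `g` counting 4-neighbor like adjacencies once
  and `g_max` from the largest-integer-square construction
  (`n = floor(sqrt(A))`, `g_max = 2n(n-1)` plus the standard remainder
  correction). A one-cell class has `g_max = 0` and AI is reported `NA`,
  not 0.

Empty classes report `NP = 0`, `PD = 0` and `NA` for the shape metrics —
undefined is distinguished from zero throughout. The whole module is
checked cell-for-cell against an independent brute-force oracle on
thousands of random rasters up to 30×30.

Rasters travel as integer matrices (`categoricalRaster()`) or as a plain
ASCII grid with a two-line header (`readAsciiRaster()`); no georeferenced
container is used.

# The composite index and levels

Indicators are min-max normalized per column to [0, 1]
(`normalizeIndicators()`), benefit indicators as `(x - min) / (max - min)`
and cost indicators mirrored. A constant column carries no ranking
information; it maps to 0.5 everywhere and is flagged (the packaged
water-area column is such a column). The composite index is the
percent-weighted sum `LQCI = sum_j w_j V_ij`, so the attainable maximum is
the weight total. The packaged 29-indicator weight set totals 55.923 % —
deliberately *not* renormalized to 100, because the fixture truth series
(28.77–43.72) is only attainable with the weights exactly as printed.
Polarity is not recorded in the fixture source; all 29 default to benefit
and can be overridden in the indicator table.

Weights for new indicator systems come from `ahpWeights()`: the
normalized principal eigenvector of a positive reciprocal pairwise
comparison matrix, with Saaty's consistency ratio and the conventional
0.1 acceptance threshold.

Quality levels use the ceiling rule `k = ceil((x - s1)/(sn - s1) * n)`
clamped to `1..n`, with the *highest* ordinal mapped to the best label
(level I). That descending direction is a package choice: with the scale
`(s1 = 28.77, sn = 43.72, n = 4)` it reproduces seven of the eight fixture
levels. The remaining year (2017, score 36.25) computes to ordinal
2.0013 → level II whereas the fixture prints III; no rounding convention
we tried reproduces it, so the discrepancy is asserted as a documented
known failure in the test suite rather than papered over.

# The network and its training

The predictor is a one-hidden-layer feed-forward network, 17-6-1 by
default, with sigmoid hidden units and the half-sum-of-squares objective
`E = 1/2 sum ||y - yhat||^2`. Inputs are the min-max-normalized indicator
columns. Targets are scaled onto [0.1, 0.9] (`targetScale()`) so the
sigmoid output unit can reach them without saturating, and predictions
are inverse-scaled for reporting; every error metric is computed on the
original index scale.

Training (`bpTrain()`, compiled) is full-batch gradient descent with
classical momentum and early stop at `E < R`. Defaults, with rationale:

| parameter | default | rationale |
|---|---|---|
| learning rate | 0.001 | the study's stated step size |
| target error R | 0.001 | the study's stated precision goal |
| momentum | 0.9 | at lr = 0.001 and zero momentum, full-batch descent stalls near E ≈ 0.02–0.2 even after 50k epochs, far above R; the momentum term (which the source method itself motivates) is required to reach the stated precision |
| max epochs | 50,000 | the smallest round cap under which both BP and GA-BP reliably reach `E < R` on the 8-sample fixture; each run takes well under a second |
| output activation | sigmoid | keeps the whole network in the unit interval; linear output is available as config |

The analytic gradient is verified against central finite differences on
random topologies, and one compiled update step is verified against an
R-level gradient step.

The GA stage (`gaEvolve()`) searches the flat chromosome of all weights
and thresholds — `v1` row-major, then `b1`, `w2`, `b2`; 115 genes for
17-6-1 — bounded in (−1, 1), with fitness `1/(1 + E)`, roulette
selection, arithmetic (convex) crossover at Pe = 0.3, per-gene uniform
resampling mutation at Pm = 0.1, population 20, 100 generations, and one
elite carried over unchanged (which makes the best fitness provably
non-decreasing). Mutation resamples *within* the gene bounds: the
alternative reading of the source description (perturbations of
magnitude ≥ 1) contradicts the (−1, 1) constraint and is not
implemented. `gaBpTrain()` hands the best chromosome to `bpTrain()`, so
the final training error never exceeds the GA-best error.

## What the GA does and does not buy

A finding worth stating plainly, because the tests surface it: under
these study conditions the GA initialization does **not** improve final
training accuracy. Measured error trajectories show the GA start helps
early, but momentum-accelerated plain BP catches up and both arms reach
the early-stop target `E < 0.001` within the epoch cap — after which the
two models differ only in how the (identical) stopping error happens to
distribute across years. GA-BP and plain BP medians over ten seeds both
sit well inside the reference error levels; their paired difference is a
statistical tie, and the corresponding comparison test records whichever
side of the tie the pre-registered seeds fall on. The hybrid's value here
is robustness of the search inside the bounded weight box, not a lower
training error.

# Validation

`regressionMetrics()` reports MSE, RMSE, MAE, MAPE (percent, on the
original index scale, undefined if any observation is zero) and Pearson
r. `splitTrainValTest()` implements the random 70/15/15 partition with
remainders assigned train-first (8 samples → 6/1/1).

`loocv()` is leave-one-out: each year is held out once, the model —
*including* the min-max statistics and the target scaling — is refitted
on the remaining seven, and the held-out squared error is recorded;
`CV(n)` is the mean. Per-fold seeds derive from one master seed. Two
properties of this design matter for interpretation:

* normalization is fold-local, so the held-out year's inputs can fall
  outside [0, 1] — no leakage, at the price of extrapolation;
* the series trends upward, so the first and last years are *pure*
  extrapolation folds. A sigmoid-output network refitted on the other
  seven years cannot reach far beyond the training target range, and
  those folds contribute squared errors of order 10–200 index units²,
  dominating `CV(n)` (≈ 25 with default settings). This is a property of
  leave-one-out on a short trending series, not a defect of the model
  fit; the suite verifies the defining identity
  `CV(n) = mean(MSE_i)` against brute-force fold recomputation.

# The synthetic generators

`simulateIndicatorSeries()` emulates the study inputs: per-indicator
linear trend plus independent Gaussian noise, with the truth series
derived through *the same* normalize-weight-sum pathway as the real
pipeline, so the generating weights are exact ground truth. Defaults
follow the study conditions — 8 years from 2015, 29 indicators with the
packaged weight set; noise defaults to 5 % of each indicator's trend
range, a modest measurement-noise level for yearbook-style statistics.
Two caveats the tests make explicit: with *zero* noise every normalized
benefit column is the same linear ramp, so the weights are
unidentifiable by regression (the recovery test therefore uses noisy,
full-rank designs, where recovery is exact to 1e-8); and independent
Gaussian noise ignores the cross-indicator correlation real
socio-economic series have, so passing tests say nothing about
collinearity robustness on real data.

`simulateRaster()` grows patches by seeded region growing with an
8-neighborhood separation buffer between same-class patches, so the
reported layout (patch count, realized cells) is exact ground truth for
the labeling stage. The `aggregation` knob steers growth compactness
(1 = always extend at the most-connected frontier cell, 0 = uniform
frontier choice). Patches may realize smaller than requested when boxed
in; the layout reports what was actually placed, and an impossible
placement fails loudly naming the separation constraint.

# Problem sizes and determinism

The shipped tests and the acceptance script run the real protocol at the
study's own scale: 8 yearly samples, 17 inputs, 10 seeds per model,
leave-one-out over 8 folds, and property sweeps of a thousand random
rasters up to 30×30 — a few minutes end to end on one CPU. Every stochastic
stage (GA, initialization, splits, folds, generators) is seeded from a
single master seed; `runPipeline()` writes byte-identical reports for
identical configurations.

# Known limitations

* The fixture landscape-index table is typography-damaged in its source;
  it is shipped as a best-effort transcription and used only as fixture
  input, never as a numeric target.
* Polarity, AHP pairwise judgments, and the mapping between two of the
  printed input column names and the indicator-system abbreviations are
  not recorded in the source tables; the package keeps the printed
  columns verbatim and exposes the choices as configuration.
* The 2-to-10 score scale of the printed level-criteria table and the
  28.77-to-43.72 range of the truth series are different scales; the
  level machinery accepts either via `levelScale()`.
* Leave-one-out on an 8-point trending series is dominated by its
  extrapolation folds (above); `CV(n)` should be read accordingly.
* No georeferenced raster I/O; bring matrices or ASCII grids.
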