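---
title: "Ensemble habitat modelling for the caterpillar fungus: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble habitat modelling for the caterpillar fungus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`yartsa` implements an ensemble species-distribution workflow for
*Ophiocordyceps sinensis* end to end, together with a synthetic world whose
habitat truth is known, so that the procedure itself — not any particular
raster archive — is the tested artifact. This vignette is the package's
account of its science: the models, the tunable parameters and their
defaults, what the generator emulates, and the choices made where the
design was genuinely open.

## 1. The data model

All spatial data live on a single-band geographic raster (`Grid`): WGS-84
degrees, square cells, row 1 northernmost, half-open cell intervals
`[edge, edge + cellSize)`. Cell areas use the spherical cosine-latitude
approximation `(cellSize · 111.195 km)² · cos(lat)` — adequate for the
relative area accounting done here (shares, gain:loss ratios, deltas) and
deliberately not a geodesic integration. Co-registered layers form an
`EnvStack`; a cell that is NODATA in *any* layer is excluded from
modelling, area sums and hotspot analysis everywhere (unioned mask). The
interchange format is the ESRI ASCII grid, chosen because it is plain text,
hand-checkable and round-trips losslessly at the printed precision.

## 2. The synthetic world and its truth

`generateEnvironment()` builds nine predictor layers in four families:
bioclimatic (Bio11 — mean temperature of the coldest quarter, °C; Bio18 —
precipitation of the warmest quarter, mm), soil (T_SILT, T_OC, T_PH_H2O),
terrain (ELE, SLOP) and land cover (HV herbaceous cover, NT needleleaf
cover). Spatial autocorrelation comes from repeated box-filter smoothing of
seeded white noise (kernel width 9 cells, 3 passes — an approximate
Gaussian); only smoothness matters to the downstream tests, so no named
geostatistical model is used. Elevation is a narrow diagonal ridge
(~2500–5500 m plus relief), Bio11 follows a 6.5 °C/km lapse rate off
elevation, Bio18 an independent steep west–east gradient, HV an alpine
meadow belt unimodal in elevation, and the soil layers are weakly
correlated noise fields. The default lattice is 200 × 200 cells of 0.05° so
every stage runs in seconds on one CPU.

The truth suitability is a logistic model on cell values:
Gaussian responses for elevation (optimum 4200 m, breadth 400 m), Bio18
(200 ± 70 mm) and Bio11 (−6 ± 4 °C), a saturating threshold response for
herbaceous cover (soft threshold 30 %), weights (7, 4.5, 2.5, 1.5) and
intercept −11.5. These defaults were calibrated once, at design time, to
make the world ecologically plausible for this species — habitat
concentrated in a cold, moderately wet alpine belt covering roughly 8 % of
the landscape. Prevalence is the load-bearing choice: a first draft with
broad responses left nearly half the landscape suitable, and with
presences drawn proportional to suitability against uniform background
even a *perfect* model then tops out near AUC 0.73. A low-prevalence world
is both the realistic emulation (real suitable area is a small fraction of
the calibration region) and the regime in which "good models score
AUC > 0.8" is meaningful. Occurrences are drawn without replacement with
probability proportional to suitability and jittered uniformly within
their cell, which guarantees no exact coordinate duplicates from sampling
(duplicates in cleaning tests are constructed explicitly).

What the generator does **not** emulate: sampling bias toward roads or
settlements, georeferencing error, spatial aggregation of survey effort,
interactions between predictors, non-climatic dispersal barriers, and real
climate dynamics (futures are offsets/multipliers plus per-GCM jitter).
Passing tests therefore demonstrate that the *procedure* recovers a known
truth under clean sampling; they do not certify performance on biased real
occurrence data.

## 3. Occurrences, pseudo-absences, splits

Cleaning removes records with non-finite or out-of-bounds coordinates
(invalid) and collapses exact-coordinate duplicates; the report satisfies
`retained = raw − duplicates − invalid` and cleaning is idempotent. No
spatial thinning is applied beyond one-record-per-cell collapse at
extraction time. Pseudo-absences are uniform random over valid cells
excluding presence-occupied cells — deliberately unrestricted (no
elevation stratification), with the exclusion buffer being the presence
cell only. The default design uses two independent sets of 1000 points.
Splits are stratified 80/20 by label with `round(fraction · n)` per class.
A master seed derives all per-(set, replicate, algorithm) seeds through a
seeded draw table, so the whole design is exactly reproducible.

## 4. Variable screening

Two tiers. (1) Pairwise Pearson correlation: while any retained pair has
|r| ≥ 0.6, the pair with the largest |r| is found and its lower-priority
member dropped; priority defaults to the per-variable mean contribution,
making the step deterministic (the convention in SDM practice when a
correlated pair must lose a member). (2) Grouped contribution screen: per
variable family, the MaxEnt-lite learner is fitted 10 times against
freshly resampled pseudo-absences (the repetition varies the
pseudo-absences — which of pseudo-absences/folds/both should vary was
open; varying pseudo-absences matches how the design's other repetitions
are built) and a variable's contribution is its normalized permutation
importance in percent; variables above 15 % are kept, then the correlation
filter re-runs within each group. Setting the contribution threshold to
zero disables the screen entirely rather than dropping
exactly-zero-importance variables, so "filter disabled" means what it
says.

## 5. Learners

Four algorithms are implemented natively and fully specified:

* **SRE** — per-variable presence quantile envelope `[q, 1−q]`
  (default q = 0.025, type-7 quantiles); predicts 1 iff all variables are
  inside, so scores are binary. Zero-width envelopes pass on equality.
* **GLM** — IRLS logistic regression on standardized linear + quadratic
  terms. Perfect separation (detected via the fitted-probability warning
  or runaway coefficients) triggers a ridge fallback (`glmnet`, α = 0,
  λ = 1e−3) recorded in the learner metadata; collinear or constant
  columns get zero coefficients rather than `NA`.
* **CTA** — Gini recursive partitioning (rpart; depth ≤ 8, leaf ≥ 5,
  cp = 1e−4); leaves predict their positive fraction. A pure-label input
  degenerates to a single constant leaf.
* **MaxEnt-lite** — logistic discrimination of presence vs background on
  standardized linear + quadratic + hinge-at-median features with L1
  penalty (default 1e−3). This is the presence/background logistic
  approximation of MaxEnt, not the full feature-class machinery; it is
  documented as an approximation and behaves correctly in its limits
  (no contrast → constant; heavy penalty → constant).

The remaining six slots of the ten-algorithm suite are contract fillers —
RF (randomForest, 100 trees), GBM (xgboost, 60 rounds, depth 3, η 0.1),
GAM (mgcv, k = 5 smooths), ANN (nnet, 5 hidden units, decay 0.01), FDA
(discriminant analysis on a quadratic basis) and MARS (logistic regression
on a quartile-knot hinge basis). The ensemble logic is agnostic to what
stands behind an algorithm id; any function returning calibrated scores in
[0, 1] can be registered. Hyper-parameters are package defaults surfaced
through the fit functions — no published defaults exist for this workflow.
Quadratic-basis learners standardize with training-set z-scores stored in
the learner.

## 6. Evaluation

AUC is the rank-based Mann–Whitney statistic (ties count ½). The
binarization threshold is the TSS-maximizing cut over candidates at
midpoints of sorted unique scores (exact on small data, no fixed grid),
ties broken toward the lowest threshold; "ROC threshold" is interpreted as
this TSS-optimal cut, consistent with the TSS-based gating that follows.
Permutation importance is `1 − cor(pred, pred with column permuted)`
averaged over permutations and floored at 0, with shares normalized to
100 % — the convention used by the major ensemble-SDM platform, adopted
because no formula is prescribed. All three are verified against
independent brute-force oracles in the test suite.

## 7. Ensemble

Runs with holdout TSS > 0.7 are gated in; variables with mean importance
> 0.1 are retained. Combiners: EMmean, EMmedian, EMca (members binarized
at their own optimal thresholds, votes averaged — values lie exactly on
`{0, 1/m, …, 1}`), EMwmean (weights `TSSᵢ/ΣTSS`; proportionality to TSS
was an open choice, made for consistency with the TSS-based gate). The
ensemble is evaluated on the pooled, deduplicated member holdouts and its
threshold re-optimized on that pool (whether published ensemble metrics
pool holdouts or re-use full data was unstated; pooling keeps evaluation
out-of-sample). The best combiner is the highest pooled TSS, ties by AUC,
then combiner order. On the synthetic world the four combiners are
statistically close (committee averaging and the mean typically within
±0.01 TSS of each other); the wide advantage a committee average can show
on real data is not a property the synthetic world reproduces, and the
suite tests the ranking mechanics rather than asserting one combiner's
dominance.

## 8. Futures, change and accounting

Per scenario, each pseudo-GCM's future stack is scored by every ensemble
member, combined, binarized at the ensemble threshold, and a cell is
consensus habitat iff **strictly** more than half of the GCMs agree (4 of
7 passes; 3 of 6 fails — the verbatim reading of "more than half"). The
headline future map intersects the consensus with current habitat (the
no-dispersal constraint, defensible for a species tied to a
limited-dispersal host). Change classification (stable/gain/loss/absent),
however, is computed against the *unconstrained* consensus: under the
strict intersection a gain is impossible by construction, while the
workflow's change maps do report gains — so the no-dispersal constraint
cannot apply to the gain/loss accounting, and both maps are emitted,
labelled. Elevation-band accounting uses the 500-m ladder
(−∞, 3000, 3500, 4000, 4500, 5000, +∞) m with gain:loss ratios reported
missing where a band loses nothing; both the current-area and union
denominators can be formed from the emitted areas. Region shares are
rounded to 1 decimal, matching how such tables are printed.

## 9. Hotspots and centroids

Getis–Ord Gi\* uses binary weights over a Chebyshev (square) window of
configurable radius (default 3 cells), self included — a fixed radius
keeps results deterministic where a GUI tool would pick a data-driven
band. The z-statistic follows the standard formulation; two-sided normal
p-values are Benjamini–Hochberg corrected across cells (the
spatial-dependence part of the inspiration tool's correction is out of
scope and said so), and confidence bins ±1/±2/±3 follow corrected
0.10/0.05/0.01 with the z sign. The input field is the continuous
ensemble suitability, not the binary map, since hotspot analysis
aggregates intensity. One caveat found during validation: a cell on the
fringe of a hot patch can be flagged hot (its neighbourhood is
significantly high) while its own value sits below the global mean, so
"hot cells all exceed the global mean" is *not* an invariant of the
statistic; the property that does hold — hot cells have z > 0, i.e.
neighbourhood mass above expectation — is what the tests assert.

Centroids are cosine-latitude-area-weighted means of habitat cell centres
(longitude wraparound unsupported; study areas are far from ±180°).
Shifts use the haversine distance on a 6371-km sphere and initial bearings
from north; climate annotation reads Bio11/Bio18 at each centroid from the
period-appropriate layers, resolving NODATA to the nearest valid cell
within 3 cells.

## 10. Economics

Production scales linearly with habitat area:
`Δproduction = production · Δarea / area`, `Δvalue = Δproduction · 1000 ·
price` with price a per-region input (no price is hard-coded; value
outputs are price-dependent by construction). Relative production change
equals relative area change exactly — the model is deliberately a
proportionality, not a yield model.

## 11. Numerical choices and degenerate inputs

* Thresholds scan exact midpoints; ties go to the lowest threshold.
* Constant score vectors give TSS 0 at the single candidate.
* Constant fields give all-zero Gi\* bins with a warning; a window
  covering the whole field degenerates to z = 0.
* Zero-variance variables are dropped from correlation filtering with a
  recorded warning; constant features in learners get zero coefficients.
* Cleaning an empty table, splitting a class with < 2 records, sampling
  more pseudo-absences than eligible cells, and combining with an unknown
  method all raise informative errors.
* Seeds: every stochastic step takes or derives an explicit seed; derived
  seeds come from a seeded `sample.int(2^31 − 2)` table.

## 12. Problem sizes in the shipped checks

The test suite and the acceptance script run the full design at sizes
chosen so the complete check remains a desk-scale computation: the
100-run count check uses a 50 × 50 world with 150 presences and 300-point
pseudo-absence sets; truth recovery runs the default 200 × 200 world with
500 presences, two 1000-point pseudo-absence sets and two replicates of
the four native learners; the learner-ordering comparison averages five
seeded worlds; the warming scenario uses a 100 × 100 world with three
pseudo-GCMs. These sizes are the package's own defaults for its shipped
validation and scale up by changing `pipelineConfig()` arguments only.

## 13. Known limitations

Single-band rasters only; no reprojection or resampling; the area model is
approximate near the poles; FDA/MARS slots are lite stand-ins honouring
the learner contract rather than reimplementations of the published
algorithms; the Gi\* correction is FDR-only; and all validation evidence
comes from a synthetic world with clean, unbiased sampling.
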