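---
title: "Modelling habitat suitability and medicinal quality with boosted regression trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling habitat suitability and medicinal quality with boosted regression trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Where should a medicinal plant be cultivated so that it both *grows well*
and *accumulates its active compounds*? For *Gentiana dahurica*, a gentian
whose roots supply the iridoids gentiopicroside, loganic acid, swertiamarin
and sweroside, the two questions have different answers: habitat suitability
is driven mainly by elevation and soil type, while compound contents track
climate (annual mean temperature, annual precipitation, temperature
seasonality). This package implements the two-part analysis that answers
both at once:

1. an **ensemble presence-background species distribution model** built on
   boosted regression trees (BRT), giving a habitat-suitability raster, an
   uncertainty (SD) raster, and per-predictor relative contributions (RC);
2. a **medicinal-quality layer** built from stepwise linear regressions of
   compound contents on the main ecological factors, applied cell-wise to
   the predictor rasters, overlaid on suitability, and cut by Jenks natural
   breaks into a four-level "high-quality growing area" map.

Because the original occurrence records and chemistry tables are not
deposited anywhere, the package ships a synthetic-data module that generates
environment stacks, a *known* true-suitability surface, occurrence records
and compound tables with the statistical structure the analysis assumes.
Every stage is therefore testable end to end without downloads — and the
ground truth is known, so the tests can ask sharper questions than any real
data set allows.

## The suitability model

### Presence cells and screened background

Occurrence records are snapped to grid cells (half-open cells,
`c = floor((x - xll)/cellsize)`, row 0 at the northern edge) and
deduplicated; the analysis works at the level of unique presence cells. The
counterpart "background" (pseudo-absence) set is *screened*, not arbitrary:
a cell is background-eligible iff it violates the agronomic suitability
band — annual precipitation strictly below 250 mm or strictly above 400 mm,
or elevation strictly below 800 m. Boundary values are not eligible; the
inequalities are strict by design. Each ensemble iteration draws a fresh
equal-size background sample (uniform, without replacement, presence cells
excluded), so with 246 presence cells every iteration trains on 492 rows.

### Boosted regression trees

The learner is gradient boosting with Bernoulli deviance, written from
scratch (with a compiled greedy splitter) because it *is* the package's
core:

* initial score `log(p/(1-p))` at the label prevalence;
* per iteration, a `bagFraction` row subsample (default 0.75, without
  replacement), pseudo-residuals `y - p`, and a regression tree with at most
  `treeComplexity` splits (default 4) grown greedily on squared-error
  improvement;
* terminal values by a one-step Newton update `sum(z)/sum(p(1-p))` over the
  in-bag rows of the leaf, clamped to `[-10, 10]` to guard separable leaves;
* the tree enters the score scaled by `learningRate` (default 0.005).

Categorical predictors are split by exhaustive subset enumeration when a
node observes at most 10 codes (exact), and by the mean-residual ordering
scan above that (for squared error the ordering scan is in fact also exact,
by Fisher's grouping argument). Codes never seen in training are routed to
the child with more training weight and counted. All tie-breaks are
deterministic: node creation order, then predictor order, then ascending
threshold — two fits with the same seed are bit-identical.

The number of trees is chosen by stratified 10-fold cross-validation grown
in `stepSize = 10` increments, minimizing pooled held-out Bernoulli
deviance, stopping after `patience = 5` non-improving steps or `maxTrees`.
The per-iteration AUC reported everywhere is the mean *held-out* fold AUC at
that optimum — never a training AUC. AUC itself is the Mann–Whitney pair
statistic (ties count one half), computed from midranks and verified in the
tests against brute-force pair counting.

### The ensemble

`runEnsemble()` repeats draw–train–predict `nIterations` times (default
200, the published design; the demonstration configuration uses 10) and
aggregates: cell-wise mean suitability, cell-wise *population* SD (the
uncertainty surface), per-iteration held-out AUC, and relative
contributions. RC is the per-predictor share of total split improvement,
normalized to 100 within each model, averaged across iterations, and
renormalized. Main ecological factors are those with RC above 2%, flagged
when their cumulative RC exceeds 95%.

## The quality model

Compound contents are linked to the continuous main factors by classic
forward-entry / backward-removal stepwise regression: enter the candidate
with the smallest partial-F p-value while it is below `pEnter = 0.05`,
remove any term whose p-value exceeds `pRemove = 0.10`, stop at a fixed
point. These thresholds are the conventional defaults of standard
statistical software and are configurable. The five published equations
(swertiamarin, gentiopicroside, sweroside, loganic acid and gentiopicroside
combined, total iridoids) ship verbatim as `builtinEquations()`, usable both
as reference fixtures and as the generative truth for synthetic chemistry.
Predictor units are a documented assumption — annual mean temperature in
deg C, seasonality as SD x 100, precipitation in mm, contents in % dry
mass — because the source prints the equations without units.

A fitted (or builtin) equation is applied cell-wise to the stack; negative
predicted contents are *retained* but counted, since the overlay normalizes
scales and clipping would silently hide extrapolation.

## Overlay and classification

The source states that compound layers were "overlaid" on suitability but
not how the layers combine. The package's choice: min–max normalize both
layers over jointly valid cells and take the cell-wise **product** — a
high-quality growing area must score high on *both* axes; `combine = "min"`
is available as the more conservative intersection. The combined score is
cut into `k = 4` classes by exact Fisher–Jenks dynamic programming
(minimizing within-class sum of squared deviations); breaks are reported as
class maxima, a value equal to a break falls in the lower class, and the DP
tie-break is fixed, so classification is deterministic and monotone. The DP
is `O(k n^2)`; above `subsample = 10000` valid cells the breaks are computed
on a seeded random subsample, below that the exact full partition is always
used.

## The synthetic scene

`demoScene()` assembles the study conditions used by the examples, the test
suite and the acceptance script:

* a 32 x 32 stack of 1-km cells with six layers named after their real
  counterparts: `bio1` (annual mean temperature, mean 5 deg C), `bio3`
  (temperature seasonality, mean 1250), `bio4` (annual precipitation,
  mean 325 mm, spanning roughly 195–455 so both sides of the 250–400 band
  are populated), `elev` (mean 1300 m, south–north gradient spanning roughly
  750–1850 so the 800 m screening floor and the 1500 m truth threshold both
  bite), `soil` (five Voronoi patches), and an inert `srad` control layer.
  Continuous layers are gradient + moving-average-smoothed Gaussian noise
  (width 3 cells), giving spatial autocorrelation like real climate grids;
* a ground truth
  `plogis(6 * (s_elev + s_precip + soil effect))`, with `s_elev` a logistic
  ramp crossing zero at 1500 m (width 200 m) — land above 1500 m is most
  suitable — and `s_precip` a plateau maximal inside 250–400 mm decaying
  outside (width 75 mm), matching the qualitative ecology the analysis is
  built around. Both effects carry amplitudes (default 1) so degenerate
  all-zero-effect surfaces are constructible for testing;
* 200 occurrence points drawn proportional to truth with within-cell
  jitter, deduplicated and trimmed to the first 60 presence cells;
* compound tables generated from the builtin equations plus Gaussian noise,
  with the noise SD calibrated per compound as
  `sd_signal * sqrt((1 - R2)/R2)` so the fitted R-squared lands near a
  target. The pipeline default target (0.35) sits mid-range of the printed
  fits (0.304–0.365); the parameter-recovery experiments in the test suite
  calibrate at 0.40, the upper end of the intended band, where the
  partial-F entry tests have adequate power at n = 50. Contents are clipped
  at zero (with a logged count) since negative percent-dry-mass is
  unphysical. The combined "loganic acid and gentiopicroside" response is
  generated directly from its own published equation rather than as a sum
  of two simulated contents, because no separate loganic-acid equation
  exists to build such a sum from.

All randomness flows from one master seed through `splitSeed()` (an affine
scramble modulo 2^31 - 1), with a distinct stream per stage and per
iteration: layer noise, occurrence draws, background redraws, fold
assignment and bagging never share a stream, and the whole pipeline is
reproducible from a single integer.

What the generator does *not* emulate: realistic geostatistics (variograms,
anisotropy), the actual geography of Inner Mongolia, sampling bias in
occurrence records, and measurement error structure in chemistry beyond
additive Gaussian noise. Passing tests therefore demonstrate that the
machinery is correct and well-calibrated under known truth — not that the
published regional maps are reproduced, which would require the undeposited
occurrence set and the WorldClim/RESDC rasters.

## Numerical choices and degenerate inputs

* `.asc` numbers are written with up to 17 significant digits, so
  write–read round trips are exact; nodata is compared exactly after
  parsing, defaulting to -9999; the `XLLCENTER` dialect is converted to the
  corner convention on read.
* Split search requires a strict improvement (> 1e-12) and at least
  `minObs = 10` rows per child (the demonstration/test configurations relax
  this to 5 at their smaller sample sizes); a tree that cannot split
  becomes a pure intercept adjustment.
* Stepwise regression skips perfectly collinear candidates (rank check)
  with a log entry; a constant response is a degenerate-fit error; an exact
  fit short-circuits the p-value at 0.
* Single-class training labels, all-zero suitability, empty record lists,
  overlapping presence/background sets, constant layers in the overlay, and
  insufficient background cells all raise early, named errors.
* Ensemble iterations that fail are skipped and logged; more than 10%
  failures aborts the run.

## Scale of the shipped experiments

The demonstration configuration (32 x 32 grid, 60 presence cells, 10
iterations, 500-tree budget, learning rate 0.005) is the package's chosen
desk-scale study design: large enough that the ensemble's held-out AUC and
RC ranking are informative, small enough to run interactively. The full
published design (200 iterations, 10,000-tree budget) is the default of
`runEnsemble()` itself and differs from the demonstration only in those two
scalars.

## Known limitations

* Permutation importance is not implemented; relative contribution is the
  only importance measure, mirroring the method the analysis defines.
* The overlay's combine rule is a design choice (product of normalized
  layers); the source does not state one.
* No CRS handling or resampling: layers must arrive pre-aligned, as the
  analysis assumes.
* Published grouped RC figures contain internal inconsistencies (a printed
  soil-group total that does not follow from the printed table; two
  variants of the soil-type RC differing in the second decimal); the
  package reproduces the table-derivable numbers and leaves the
  discrepancies unresolved.
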