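---
title: "Bias-weighted boosted regression tree ensembles for species distribution modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-weighted boosted regression tree ensembles for species distribution modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

`macrosdm` implements a presence-only species distribution modelling
(SDM) workflow of the kind used to map habitat suitability for
poorly-surveyed taxa — the motivating case being African mound-building
termites whose occurrence records are sparse, historical and spatially
biased toward well-collected regions. The workflow is:

1. thin occurrence records to one presence per grid cell on a
   2.5-arcminute lon/lat lattice;
2. draw pseudo-absences from the modelling region with probability
   proportional to a survey-effort ("bias") surface, with as many
   absences as presences;
3. fit a boosted regression tree (BRT) model to each presence/absence
   table, selecting the number of trees by cross-validated predictive
   deviance;
4. repeat the pseudo-absence draw and fit 100 times and average:
   suitability per cell, relative influence per covariate, AUC and
   deviance explained across replicates;
5. project the replicate models onto future-scenario covariates and
   quantify the change in "very suitable" area — cells within 15% of the
   current maximum suitability — in square kilometres.

Because real occurrence data and versioned climate rasters are external
inputs, everything here is validated on *virtual species*: simulated
covariate stacks and occurrence sets whose ground truth (which variables
drive suitability, and how strongly) is known exactly.

## The model

For a binary label $y \in \{0,1\}$ (presence vs pseudo-absence) with
covariate vector $x$, the BRT models the log-odds as an additive
expansion of regression trees,

$$ f(x) = f_0 + \sum_{m=1}^{M} \nu \, T_m(x), $$

where $f_0$ is the empirical log-odds intercept, $\nu$ the learning
rate, and each $T_m$ a small regression tree fitted to the gradient of
the Bernoulli log-likelihood (the residual $y - p$), with leaf values
given by a Newton step $\sum (y-p) / \sum p(1-p)$ over the leaf's bagged
rows. Trees are grown best-first with exactly `tree_complexity` splits,
each split chosen to maximize the squared-error reduction of the
residuals; categorical predictors (the biome layer) split on level
subsets ordered by mean residual, which is optimal for squared error.

The number of trees $M$ is not a free parameter: trees are added in
stages of `step_size` per cross-validation fold, the mean held-out
deviance is recorded per stage, and $M$ is the stage minimizing that
curve. A final model with $M$ trees is refitted on all rows. The
cross-validated AUC is the Mann–Whitney statistic of the out-of-fold
predictions at the selected stage. Deviance explained is
$1 - D_{cv}/D_0$ with $D_0$ the intercept-only deviance.

Relative influence of a covariate is the sum of split improvements over
all splits using it, across the final model's trees, normalized to
percentages summing to 100.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tree_complexity` | 3 | splits per tree (interaction depth) |
| `learning_rate` | 0.002 | shrinkage per tree |
| `bag_fraction` | 0.75 | share of rows subsampled per tree |
| `step_size` | 50 | trees added per CV stage |
| `cv_folds` | 10 | stratified cross-validation folds |
| `max_trees` | 10000 | hard cap |
| `patience` | 5 | stages without improvement before stopping |
| `min_obs` | 5 | minimum rows per tree node |

The staged defaults (50-tree steps, 10 folds, 0.75 bagging) follow the
standard staged BRT fitting procedure for ecological SDMs.
`select_hyperparameters()` reproduces the conventional grid rule: try
tree complexities 1–7 and learning rates 0.001–0.003, keep the
complexity with the lowest minimum CV deviance, and among its rates the
largest one whose selected model used more than 1000 trees. `min_obs`
is set to 5 rather than the conventional 10 because the package targets
desk-scale tables (a few hundred rows) where 10 can block informative
splits on small leaves. The stopping rule (`patience`) bounds runtime
with a plateau detector; because the CV-deviance minimum is what is
reported, a longer run can only confirm the same selection.

Ensemble replicate $r$ seeds the RNG with `seed + r`, giving
independent, bit-reproducible pseudo-absence draws, fold assignments
and bagging per replicate. Hyperparameters, when searched, are selected
once on the first replicate's table and reused — re-searching per
replicate would multiply cost 21-fold while Table-style reporting
assumes one tree count per species.

## The virtual-species generator

`generate_covariates()` builds each continuous layer as an equal mix of
a random-orientation linear gradient (the large-scale climatic trend)
and Gaussian-kernel-smoothed noise (local structure), rescaled to
plausible ranges for the seven canonical climate covariates. Requested
cross-covariate correlations are imposed exactly by orthogonalizing and
remixing the standardized fields — the default demo requests r = 0.72
between mean annual and minimum temperature, the maximum collinearity
regime the screening step is meant to flag (threshold 0.7, report-only:
trees tolerate collinearity, and dropping variables is a judgement
call left to the analyst). The biome layer is cut from an independent
smooth field at quantiles, so every code is present.

A virtual species is a logistic suitability surface
$p = \operatorname{plogis}(\beta_0 + \sum_v \beta_v z_v + b_{biome})$
over z-scored covariates. Presences are drawn without replacement with
probability proportional to $p$ and jittered uniformly inside their
cell, so thinning recovers the sampled cells exactly.

The default strong-signal species uses $\beta_{min\_temp} = 6$ with
intercept $-9$. This places the species' envelope in the upper tail of
the covariate (occupied cells sit roughly 1.5 standard deviations above
the regional mean) — the regime that corresponds to a species tightly
constrained by one climatic factor relative to the continental
background. A weaker, higher-prevalence species (say
$\beta = 2.5, \beta_0 = -0.5$) overlaps the background so much that
even the true suitability surface cannot discriminate presences from
background cells beyond AUC ≈ 0.7; discrimination near 0.99, as
reported for well-modelled real species, is only attainable in the
narrow-envelope regime, which is why it is the default for validation.

The bias surface emulates a continental record-density map: 25
Gaussian effort hotspots over a uniform floor of 0.2, so every cell is
reachable as a pseudo-absence but well-surveyed areas are strongly
preferred. With the floor at 0 (and smoothing 0), zero-effort cells are
never drawn — the strict reading of effort-proportional weighting; an
additive smoothing constant is exposed for sensitivity analysis.

What the generator does *not* emulate: real African geography,
anisotropic climate gradients, spatially autocorrelated recording
effort along roads and rivers, coordinate uncertainty in historical
records, and taxonomic confusion. Passing recovery tests on virtual
species therefore shows the machinery is correct and unbiased under
the generator's assumptions, not that any real-data inference is right.

## Geodesy and raster conventions

Grids are anchored so that −180° and −90° fall on cell edges (the
WorldClim registration); cells are half-open boxes with west and north
edges inclusive, row 1 northernmost, so point-in-cell assignment is
total and deterministic. Cell areas use the spherical-zone formula
$A = R^2\,\Delta\lambda\,(\sin\varphi_{top} - \sin\varphi_{bottom})$
with the IUGG mean radius $R = 6371.0088$ km; the sphere-vs-ellipsoid
error (< 0.3%) is far below the uncertainties of any SDM area
statistic. Rasters are read and written as single-band ESRI ASCII
grids — a plain-text geographic format carrying the registration and a
nodata value (−9999) — with 17 significant digits so round trips are
bit-exact. Layer alignment is enforced to 1e-9 degrees: loose enough to
absorb float noise, tight enough to reject genuinely shifted grids.

## Numerical choices and degenerate inputs

* Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ inside the
  deviance; Newton leaf steps are capped at ±10 against vanishing
  Hessians under perfect separation.
* CV deviance ties select the earlier stage (fewer trees); equal split
  improvements keep the first candidate in scan order, which is
  deterministic.
* A constant covariate has undefined Pearson correlation: the screen
  reports it as `NA` rather than erroring.
* Replicates that fail (for example, a degenerate pseudo-absence draw)
  are skipped and logged; more than 10% failures aborts the ensemble.
* Unseen biome codes at prediction time are routed to the
  training-majority branch of each split, with a message.
* "15% below the current maximum" is read multiplicatively: the
  threshold is $0.85 \times \max_{current}$, which stays inside
  $[0, 1]$ for species whose maximum suitability is low (a subtractive
  reading could produce a negative threshold). The current maximum is
  computed inside the analysis mask and reused unchanged for future
  maps, so current and future areas are cut at the same absolute level.
* The projection analysis region ("limited predictions based on
  distribution data") is the presence bounding box buffered by 5° by
  default — an explicit, reproducible stand-in for map-based judgement.
  Exclusion of biologically irrelevant areas is user-supplied as a
  raster mask; no automatic inference is attempted.

## Problem sizes used in validation

The test-suite and acceptance runs use a 100×100-cell world at
2.5 arcminutes (≈ 4.17° square), 150 presence records, and ensembles of
25 replicates for the 20-seed driver-recovery checks (100 replicates
for the determinism and demonstration runs). These sizes keep a full
validation sweep in the minutes range on one core while leaving every
statistical property of the full-scale workflow intact; the ensemble
size only tightens the across-replicate means, so scaling down
replicates widens tolerance bands rather than changing expectations.

## Known limitations

* No reprojection: inputs must already be geographic lon/lat on a
  shared grid.
* No dispersal, land-use or habitat-transformation modelling; the area
  statistic is climate-envelope change only.
* Categorical predictors are limited to 64 levels (bitmask splits).
* The weighted without-replacement pseudo-absence draw uses sequential
  sampling (successive draws proportional to remaining weight), the
  standard behaviour of `sample()`; for draw sizes close to the
  candidate-pool size inclusion probabilities deviate from exact
  proportionality, which is immaterial at SDM scales where candidates
  vastly outnumber presences.
* Partial-dependence surfaces and tree-simplification are out of
  scope; the ensemble reports influence, AUC, deviance and maps only.
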