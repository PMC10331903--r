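# macrosdm

Bias-weighted boosted regression tree ensembles for presence-only
species distribution modelling, with future-scenario projection and
geodesic accounting of "very suitable" area change.

## What problem this solves

Occurrence records for poorly-surveyed taxa — the motivating case being
African mound-building *Macrotermes* termites — are sparse, historical,
and concentrated where collectors went, not where the species lives.
`macrosdm` implements the standard SDM answer to that situation as a
tested, reproducible pipeline:

1. **Thin** occurrence records to one presence per cell of a
   2.5-arcminute lon/lat grid.
2. **Draw pseudo-absences** from the modelling region with probability
   proportional to a survey-effort ("bias") raster, as many absences as
   presences, so absences carry the same recording bias as presences.
3. **Fit a boosted regression tree** (BRT) to each presence/absence
   table: forward-stagewise boosting of the Bernoulli log-likelihood,

   f(x) = f₀ + ν Σₘ Tₘ(x),

   where each tree Tₘ (exactly `tree_complexity` splits) is fitted to
   the gradient y − p on a bagged subsample and shrunk by the learning
   rate ν. The number of trees is selected at the minimum of the mean
   10-fold cross-validated predictive deviance; model skill is the
   cross-validated AUC (Mann–Whitney form) and deviance explained,
   1 − D_cv/D₀.
4. **Ensemble**: repeat the absence draw and fit 100 times and average
   suitability per cell, percentage relative influence per covariate
   (split-improvement shares summing to 100), and AUC/deviance across
   replicates.
5. **Project** all replicate models onto future climate layers
   (e.g. SSP scenarios) and quantify the change in *very suitable*
   area — cells within 15% of the current maximum suitability — in km²
   (spherical-zone cell areas, R = 6371.0088 km) and percent.

A virtual-species simulator (`generate_covariates()`,
`virtual_species()`, `sample_virtual_occurrences()`,
`generate_bias_layer()`) produces covariate stacks, effort surfaces and
occurrence sets with known ground truth, so the entire pipeline is
validated end-to-end without any external downloads. Rasters are read
and written as plain-text single-band ESRI ASCII grids.

## Worked example

```r
library(macrosdm)

# a 100x100-cell synthetic world at 2.5 arcminutes
grid  <- build_grid(20, -20, 24.1666, -15.8334, resolution_arcmin = 2.5)
stack <- generate_covariates(grid, seed = 7,
  correlations = list(list(pair = c("mean_annual_temp", "min_temp"),
                           rho = 0.72)))
bias  <- generate_bias_layer(grid, hotspots = 25, seed = 8, floor = 0.2)

# a virtual species driven by minimum temperature
species <- virtual_species(coefficients = c(min_temp = 6),
                           intercept = -9, n_presences = 150)
suit <- true_suitability(stack, species)
set.seed(11)
occ  <- sample_virtual_occurrences(suit, species)
presences <- thin_to_grid(occ, grid)
presences
#> sdm_presences: Virtualis exempli, 150 cells (from 150 in-grid records)

collinearity_screen(stack)
#> collinearity screen (|r| > 0.7): 1 flagged pair(s)
#>               var1     var2    r
#> 1 mean_annual_temp min_temp 0.72

ens <- run_ensemble(presences, bias, stack,
                    brt_config(tree_complexity = 3, learning_rate = 0.005,
                               max_trees = 2000),
                    n_replicates = 25, seed = 1)
ens
#> sdm_ensemble: Virtualis exempli, 25 replicate(s), AUC 0.934 +/- 0.015, 150 presences
#>   top influence: min_temp (88.4%)

round(ens$mean_influence, 2)
#>   mean_annual_temp           min_temp           max_temp         temp_range
#>               1.95              88.35               1.32               1.95
#>      diurnal_range      annual_precip precip_seasonality              biome
#>               1.71               1.81               2.00               0.89

# identity-scenario projection: exactly zero change by construction
fut <- project_scenario(ens$models, stack)
ref <- suitability_max(ens$mean_suitability)
suitability_change(very_suitable_mask(ens$mean_suitability, ref),
                   very_suitable_mask(fut, ref),
                   species = "Virtualis exempli", scenario_id = "identity")
#> sdm_change Virtualis exempli [identity]: 17961 -> 17961 km2 (delta +0 km2, +0.00%)
```

The ensemble recovers the simulated ground truth: the species was
built on minimum temperature alone, and minimum temperature carries
88% of the mean relative influence with a cross-validated AUC of 0.93;
the 0.72 covariate correlation injected into the stack is flagged by
the screen at the conventional 0.7 bound (screening is report-only).

For file-based workflows, `sdm_simulate()`, `sdm_fit()` and
`sdm_project()` run the same pipeline from a YAML/list configuration,
writing suitability rasters, the per-species influence table,
per-replicate diagnostics, change reports and a manifest with input
hashes and seeds; `inst/cli/sdm.R` is a thin command-line front-end
over those three functions.

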