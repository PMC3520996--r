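# abaclim

Projecting the distribution and abundance of harvested abalone under ocean
warming: an end-to-end, fully testable R implementation of the
climate-to-fishery projection chain, for quantitative ecologists and
fisheries scientists who need each stage — climate-model selection,
downscaling, ensemble species distribution modelling, range products and the
physiological overlay — as reusable, seeded, unit-tested functions.

## What it computes

Two species with contrasting thermal responses to winter (August)
sea-surface temperature are modelled from count surveys (individuals per
100 m²):

- blacklip: log E[N] = β₀ + β₁·SST + covariates (monotone response),
- greenlip: log E[N] = β₀ + β₁·SST + β₂·SST² + covariates, β₂ < 0
  (hump-shaped, optimum −β₁/2β₂ ≈ 17 °C),

with negative-binomial counts, fitted both as a GLM and as boosted
regression trees and combined with validation-deviance weights
w ∝ exp(−Δ/2). Future August SST comes from a skill-ranked GCM ensemble:
models are scored against an observed climatology by bias, pattern
correlation, and standard and centred RMSE (rmse² = bias² + crmse²), ranked
per statistic, summed to a cumulative rank, and the top five averaged. The
coarse (2.5°) ensemble anomaly is bilinearly refined to 0.5° and added to a
fine (0.01°) baseline built by thin-plate-spline smoothing with
GCV(λ) = n·RSS/(n − tr H)² — the change-factor method. Projected abundance
at each decade yields potential fishing grounds (≥ 20 individuals / 100 m²),
retained/gained/lost/never change maps, and percent change in harvestable
abundance. A March (late-summer) overlay bins projected SST into < 17,
[17, 20) and ≥ 20 °C tolerance categories — 20 °C being the temperature at
which juvenile mortality rises ~19-fold (58.12 % vs 3.1 %; one-way ANOVA on
tank replicates, F(1,6) ≈ 36) — bounding how much projected expansion is
thermally realistic.

Every input can be generated synthetically with a known ground truth
(`generate_baseline()`, `generate_gcm_anomalies()`, `generate_surveys()`,
`generate_mortality()`), so the whole chain is testable offline. See
`vignettes/methods.Rmd` for the full model description and design choices.

## Worked example

```r
library(abaclim)
tr  <- synthetic_truth()
dom <- domain_geometry(nrow = 60, ncol = 100)          # 0.01 deg cells
aug <- generate_baseline(dom, "august", tr, noise_sd = 0.3, seed = 1)
aug
#> <raster_grid> sst_august: 60 x 100 cells at 0.01 deg, origin (130, -36)
#>   sea cells: 4360 / 6000; range 12.125 .. 20.473

# fit the greenlip ensemble on synthetic surveys (80/20 train/validation)
sv  <- generate_surveys(aug, tr, n_records = 2000, species = "B", seed = 2)
glm_fit <- fit_glm(sv[1:1600, ], "quadratic")
brt_fit <- fit_brt(sv[1:1600, ], seed = 3)
ens <- sdm_ensemble(glm_fit, brt_fit,
                    ensemble_weights(glm_fit, brt_fit, sv[1601:2000, ]),
                    species = "B")
thermal_optimum(glm_fit)
#> [1] 17.04398
```

The fitted optimum recovers the generator's 17 °C truth. Rank six emulated
climate models against the observed baseline and project 2100 abundance
under the high-emissions Reference scenario (WRE750):

```r
rk <- rank_models(skill_table)   # one skill_stats() row per model
rk[, c("model", "bias", "pattern_correlation", "rmse", "cumulative_rank")]
#>   model      bias pattern_correlation  rmse cumulative_rank
#> 1 model_01 0.0500               0.998 0.113               4
#> 2 model_02 0.0995               0.993 0.224               8
#> ...

an  <- generate_gcm_anomalies(6, decades = 2100, scenario = "WRE750",
                              truth = tr, seed = 4, domain = dom)
proj_sst <- change_factor(aug, bilinear_refine(
  select_and_average(an, rk, k = 5)$grid[[1]], 0.5))
cur <- predict_abundance(ens, aug)
fut <- predict_abundance(ens, proj_sst)
percent_change_above_threshold(cur, fut, 20)
#> [1] -20.17139
classify_change(delineate_grounds(cur, 20), delineate_grounds(fut, 20))
#> <fishing_ground_map> threshold 20 /100m2
#>   category n_cells
#> 1 never       1518
#> 2 lost        1126
#> 3 gained       717
#> 4 retained     999
```

For this hump-shaped species, +1.1 °C of winter warming *redistributes*
habitat: grounds are gained on the cool flank but more are lost past the
optimum, and harvestable abundance falls ~20 %. (The linear-responding
blacklip gains instead.) The mortality experiment's statistics, rebuilt from
the reported summaries alone:

```r
anova_from_summary(means = c(3.1, 58.12), ses = c(3.1, 8.6), n = 4)
#> One-way ANOVA: F(1,6) = 36.2235, p = 0.000949
fold_change(58.12, 3.1)
#> [1] 18.74839
```

`run_pipeline(pipeline_config(...))` chains all stages (synthetic inputs →
GCM ranking → downscaling → SDM fit → decadal projection → range/overlay
products → mortality statistics) into plain-text artifacts with an MD5
manifest; identical configs reproduce identical bytes.

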