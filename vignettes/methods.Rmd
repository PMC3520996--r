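---
title: "Methods: projecting abalone abundance under ocean warming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting abalone abundance under ocean warming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abaclim)
```

## The problem

Two commercially harvested abalone species — blacklip (*Haliotis rubra*) and
greenlip (*H. laevigata*) — occupy overlapping ranges along a temperate
southern coastline. Their abundance responds to winter (August) sea-surface
temperature (SST): log-linearly for blacklip, and with a hump-shaped
(quadratic, optimum near 17 °C) response for greenlip. Warming winters are
therefore expected to raise abundance and expand potential fishing grounds.
The catch is the late summer: juvenile mortality rises roughly an order of
magnitude once March SST reaches 20 °C, so the same warming that improves
winter habitat can make the newly suitable area lethal to recruits.
`abaclim` implements the full chain needed to quantify both sides of this
trade-off, end to end, with a synthetic-data module that supplies every input
with a known ground truth.

The pipeline has six scientific stages:

1. **Climate-model skill ranking** (`skill_stats()`, `rank_models()`,
   `outlier_analysis()`, `select_and_average()`): candidate GCM fields are
   scored against an observed climatology with four statistics — bias,
   pattern correlation, and standard and centred root-mean-square errors —
   converted to ranks (1 = best), summed into a *cumulative rank*, screened
   for outliers, and the best *k* (default 5) models' anomaly fields averaged
   cell-wise without weights.
2. **Baseline climatology smoothing** (`tps_fit()`, `tps_evaluate()`): a
   thin-plate spline with generalized cross-validation (GCV) turns noisy
   point samples of SST into a smooth fine-resolution (0.01°) baseline.
3. **Change-factor downscaling** (`bilinear_refine()`, `change_factor()`):
   the coarse (2.5°) ensemble anomaly is bilinearly refined to 0.5° to soften
   grid-box edges, then added directly to the fine baseline; each 0.01° cell
   inherits the anomaly of its nearest 0.5° parent, so all fine-scale spatial
   structure of the baseline is preserved exactly.
4. **Ensemble abundance models** (`fit_glm()`, `fit_brt()`,
   `ensemble_weights()`, `predict_abundance()`, `project_decades()`): a
   negative-binomial GLM (log link) and a boosted-regression-tree model are
   fitted to abundance surveys and combined with validation-deviance weights;
   projections at each decade substitute the downscaled future August SST
   while holding all non-climate covariates at their training values.
5. **Fishing-ground and overlay products** (`delineate_grounds()`,
   `classify_change()`, `percent_change_above_threshold()`,
   `march_overlay()`, `density_by_temperature_bins()`): cells at or above 20
   individuals / 100 m² are potential fishing grounds; present/future
   cross-tabulation yields retained / gained / lost / never maps; March SST is
   binned into < 17, [17, 20) and ≥ 20 °C tolerance categories per region.
6. **Juvenile-mortality statistics** (`one_way_anova()`,
   `anova_from_summary()`, `fold_change()`): a tank-level one-way ANOVA of
   the two-temperature (17 vs 20 °C) mortality experiment, including exact
   reconstruction of the F statistic from group means, standard errors and
   group sizes alone.

`run_pipeline()` orchestrates the stages from a single `pipeline_config()`
with per-stage seeds, plain-text artifacts (ESRI ASCII grids, CSV, JSON) and
an MD5 manifest; rerunning an identical config reproduces every artifact
bit-for-bit. The package is used from R; the config-driven stage runner is
the pipeline's operational interface.

## What the synthetic data emulate — and what they do not

All generators are pure functions of their parameters and a seed.

**Baseline climatology** (`generate_baseline()`): a closed-form smooth
surface (west–east warming, south–north cooling, low-order harmonics) plus
iid Gaussian observation noise (default sd 0.3 °C), masked to sea by a
procedural undulating coastline. August spans roughly 12–20 °C. The March
field is August plus a spatially varying offset of ~2.1–2.7 °C
(`march_offset` = 2.5), so March spans roughly 14–23 °C. The offset is
deliberately sized so that the greenlip August optimum (17 °C) falls inside
the 17–20 °C March band while the warm end of the domain lies ~3 °C beyond
it: this reproduces the observed thermal structure in which present-day
densities peak between March 17 and 20 °C and decline where March reaches
20 °C — the premise of the tolerance overlay. A domain without warm-edge
habitat would make that decline (and the linear-vs-quadratic model contrast)
undetectable in principle, not just in noise.

**GCM anomalies** (`generate_gcm_anomalies()`): per model, the scenario
trajectory plus a constant model offset (iid Gaussian, sd `spread_sd`,
default 0.15 °C) plus a smooth model-specific spatial perturbation, on a
2.5° grid covering the domain. The Reference scenario (WRE750) warms
0.11 °C/decade (≈ +1.1 °C by 2100); the Policy scenario (LEV1) warms
0.046 °C/decade, or optionally peaks at +0.46 °C in 2080 easing to +0.44 °C
by 2100 (`policy_shape = "peak_decline"`). An optional planted outlier model
(`outlier_bias`) exercises the outlier analysis. Anomalies arrive already
standardised for climate sensitivity: the gas-cycle/climate model that would
produce them is an emulation boundary, not part of the package.

**Abundance surveys** (`generate_surveys()`): records on distinct sea cells;
depth uniform on 5–30 m (the surveyed depth band); harvest intensity uniform
on 0–1 and distance-to-launch uniform on 0–50 km (no observed ranges exist
for these, so both are documented artifacts of the emulation); counts
negative-binomial (dispersion 5) around the log-linear truth. Default truth:
blacklip intercept 3.6 and SST slope 0.15 (centred at 15 °C); greenlip
intercept 3.9 and curvature −0.12 (centred at the 17 °C optimum); depth
−0.02 / m, harvest −0.5, distance −0.005 / km. Intercepts were chosen so
present-day peak densities (~25–45 / 100 m²) straddle the 20 / 100 m²
harvest threshold, as in the real fishery — both species then have
present-day grounds, gains under warming, and (for greenlip) warm-edge
losses.

**Mortality experiment** (`generate_mortality()`): per-tank mortality
percentages, Gaussian truncated to [0, 100], default two groups (17 and
20 °C) of 4 tanks with means 3.1 and 58.12 % and SDs 6.2 and 17.2 %
(SE·√4 of the reported summaries).

Not emulated: satellite artifacts (cloud gaps, day/night passes), larval
dispersal and connectivity, bathymetry, variance changes under warming
(change factors perturb means only), and any demographic/metapopulation
coupling. Passing tests therefore demonstrate the *procedure* is correct and
well-calibrated on data whose generating process is known — not that the
real system satisfies the models' assumptions.

## Numerical and statistical choices

**Thin-plate spline.** Classical 2-D kernel \(r^2 \log r\) plus an affine
part; the penalized augmented system is solved densely for each candidate
\(\lambda\) on a log-spaced grid spanning eight decades (1e-6–1e2 by
default), and the influence matrix is formed explicitly, so
\(\mathrm{GCV}(\lambda) = n\,\mathrm{RSS}/(n - \mathrm{tr}\,H)^2\) uses the
exact trace. Candidates with non-positive residual degrees of freedom
(numerically, below 1e-8) are rejected; if all are rejected — e.g. a single
tiny \(\lambda\) on noiseless data — the smallest-\(\lambda\) (interpolating)
fit is returned with an infinite GCV score. Affine surfaces are reproduced
exactly for every \(\lambda\) (they live in the penalty's null space).
Dense algebra limits fits to roughly 2000 knots; pipeline fits use 250.

**Downscaling.** The 0.5° → 0.01° anomaly transfer uses the nearest parent
cell by default (the anomaly is *added directly*; the 0.5° step exists only
to soften coarse grid-box boundaries), making projected − baseline exactly
piecewise constant on 0.5° blocks; `method = "bilinear"` is available where
a second interpolation is preferred. Fine coastal cells whose nearest parent
falls just outside (or on an invalid cell of) the anomaly grid snap to the
nearest valid parent within one cell; farther gaps are an error, since they
indicate a genuine coverage problem rather than coastal clipping.
Bilinear refinement extrapolates by edge clamping, which preserves the
bounded-by-neighbours property.

**Skill ranking.** Bias is ranked by absolute value (a cold model is as
wrong as a warm one); ties take averaged ranks (the standard rank-statistics
convention, keeping cumulative ranks comparable); the four statistics enter
the cumulative rank with equal weight; the top-k average is unweighted.
The statistics satisfy rmse² = bias² + centred-rmse² identically, which the
tests enforce to 1e-9.

**Abundance models.** Negative binomial with log link is the default family
(abundance counts are overdispersed; Poisson is a config option). The
quadratic SST term is centred to decorrelate it from the linear term; the
implied thermal optimum is `sst_center` − b₁/(2 b₂). BRT defaults follow
standard ecological practice: depth 3, learning rate 0.01, bag fraction 0.5,
up to 2000 trees with early stopping on a 20 % holdout, single-threaded and
seeded for exact reproducibility; the response is log1p(count) under squared
error. Ensemble weights are \(w_i \propto \exp(-\Delta_i/2)\) on validation
deviance (an information-criterion-style weighting that reduces to equal
weights for equally skilled components; Δ > 20 effectively removes a
component); `scheme = "equal"` is available. At prediction time every
non-SST covariate is fixed to its training mean — only SST has future
forecasts — and harvest intensity is held at current levels across decades.

**Range products.** The fishing-ground threshold (20 / 100 m²) is inclusive
(≥). March tolerance bins are left-closed: < 17, [17, 20), ≥ 20 °C, with 17
placed in the middle bin — the source material mixes "at or below 17" with
"exceeds 17", so the package fixes one convention and exposes the edges in
config. The "current distribution" mask uses a present-day predicted
abundance above 0.5 / 100 m² (configurable); "expansion cells" are the
gained class of the change map. Overlay fractions are cell fractions by
default; cosine-latitude area weighting is available
(`area_weighted = TRUE`) since cells on a lat/lon grid differ slightly in
true area. Box-plot summaries use type-7 (linear interpolation) quantiles.

**Mortality ANOVA.** The tank is the unit of replication — 4 tanks per
temperature give df (1, 6); individuals within tanks are pseudo-replicates
and never enter the analysis. Percentages are analysed untransformed
(matching the reported analysis); an arcsine or logit transform can be
applied upstream if desired. `anova_from_summary()` reconstructs SD as
SE·√n and is algebraically identical to the raw-data ANOVA on any data with
those summaries, which the tests verify to 1e-10; reconstruction from the
reported rounded summaries gives F ≈ 36.2 against the reported 35.96, the
~0.7 % gap being attributable to rounding of the printed means and SEs. The
reconstructed p is reported at full precision (≈ 9.5e-4) rather than as a
floor. With zero within-group variance the F statistic is reported as an
explicit infinity flag with p = 0.

## Problem sizes and calibration checks

The test suite regenerates all fixtures in code. Representative sizes,
chosen to make the statistical properties sharp while keeping the suite
quick: GLM coverage uses 50 synthetic surveys of n = 2000 (each true
coefficient must fall in its 95 % Wald CI in ≥ 90 % of seeds); thermal
optimum recovery averages 20 quadratic fits of n = 2000 (tolerance
±0.5 °C); GCV-vs-interpolation uses 20 noisy-plane fits of n = 200; the
ANOVA's type-I error is estimated from 10,000 simulated null experiments
(required within 0.05 ± 0.01); brute-force range-product oracles run on
10⁴-cell grids; the smoke pipeline runs a 30×50-cell domain with 6 GCMs,
2 decades and 2 scenarios. `scripts/acceptance.R` recomputes the headline
quantities from scratch at the same sizes.

## Known limitations

- Only geographic lat/lon grids with cell-centre registration; the on-disk
  format is the plain-text ESRI ASCII grid (no GeoTIFF/NetCDF driver is
  linked in this build, and no vector coastlines).
- Change-factor downscaling perturbs means only; GCM variance and extremes
  are not bias-corrected.
- The anomaly fields are treated as month-agnostic within a scenario: the
  same ensemble anomaly perturbs the August and March baselines, consistent
  with the trajectories differing by month mainly through their baselines at
  the scales emulated here.
- The SDM ensemble contains exactly two components (GLM, BRT); the weighting
  generalises but no other algorithms are implemented.
- TPS fitting is dense (exact GCV traces) and practical to ~2000 knots.
- Projections are correlative: no recruitment, dispersal or
  harvest-dynamics feedback. The March overlay bounds how much of the
  projected expansion is thermally realistic; it does not model mortality
  spatially.
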