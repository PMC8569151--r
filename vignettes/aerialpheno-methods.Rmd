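---
title: "Methods: aerial estimation of peanut LAI and lateral growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aerial estimation of peanut LAI and lateral growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerialpheno)
```

## The estimation problem

Healthy peanut leaves absorb in the blue and red and reflect in the green,
so the canopy's RGB reflectance carries information about leaf area index
(LAI, dimensionless) and lateral growth (LG, cm). The pipeline turns raw
per-plot digital numbers (DN) from an orthomosaic into reflectance, then
into six vegetation indices, then into trait estimates:

DN → (panel calibration) → reflectance → (Table of index formulas) → VIs →
(linear or neural model) → LAI / LG.

## Zonal extraction

A plot belongs to the fishnet as a simple polygon in world coordinates. A
pixel contributes to a plot's mean DN iff its **centre** lies inside the
polygon, boundary inclusive. The centre rule is deterministic and matches
common zonal-statistics semantics; the original workflow's inclusion rule is
not recorded, so this was a genuinely open choice. The test suite checks the
implementation against an independent winding-number brute-force loop, and
checks invariance under common world translations of raster and fishnet.

For two-row plots, calibrated **reflectance** of the two rows is averaged to
plot level (`average_rows_to_plot()`) — averaging happens after calibration
and before index computation, not at DN or VI level.

Rasters travel as plain-text ESRI ASCII grids rather than GeoTIFF: the
deployment environment provides no geospatial raster stack, the dialect is
loss-free for integer DN grids, and it keeps all fixtures human-readable.
Only north-up square-cell geotransforms can be serialized, which is exactly
what an orthomosaic export is; the in-memory `band_raster` accepts any
invertible 6-term affine. No CRS reprojection is attempted (single-scene
tool).

## Panel calibration

Each band's DN→reflectance map is exponential, ρ = a·b^DN, fitted to the
8-shade panel by **log-linear least squares**: OLS of log ρ on DN gives
log a and log b in closed form. Whether the original fit was log-linear or
nonlinear least squares is unstated; the log-linear form is chosen because
it is deterministic, exact on noiseless exponential data (recovery to 1e−9
in the tests), and unbiased in log b under multiplicative reflectance noise
(verified by a 500-replicate Monte-Carlo test at σ_log = 0.05). The six
published (a, b) pairs for the 2017 and 2019 campaigns are built in via
`builtin_calibrations()`. Calibrated reflectance can exceed 1 at high DN;
values are returned unclamped with a warning, since the source workflow
never mentions clamping.

## Vegetation indices

All six indices are reflectance ratios, hence invariant to a common band
rescaling (tested property). The normalized differences NGRDI, PPR and NCPI
mathematically lie in (−1, 1); empirical summaries that print their range as
0–1 are treated as observations about field data, not constraints, and
negative values are never clamped. Zero denominators (a nonpositive band)
yield per-plot error records rather than aborting a campaign.

## Trait models

Four frozen estimators are shipped verbatim: `reg1`/`reg3` are affine sums
of 5 / 4 indices; `reg2`/`reg4` are affine in the *product* of their
indices. `fit_linear_trait_model()` refits either form by OLS (in product
mode the single regressor is the rowwise product). Stepwise selection is
forward-backward on the SSE-form AIC, n·log(SSE/n) + 2p. The original
selection used a proprietary procedure whose entry/stay thresholds are
unrecorded; AIC forward-backward is the deterministic standard choice. On a
numerically perfect fit the SSE is floored at machine precision relative to
the response's total sum of squares, so the 2p penalty still discriminates
model sizes — this is what lets noiseless recovery runs terminate with
exactly the generating predictor set (5 for LAI, 4 for LG, never RGR).

### Multilayer perceptron

The reference network had three hidden layers of 5, 4 and 3 nodes, learning
rate 0.001, momentum 0.99 and 10,000 training iterations; everything else
about it is unrecorded. The re-implementation chooses, for determinism and
reproducibility:

* sigmoid hidden activations, **linear** output node;
* per-feature standardization of inputs and the response (undone at
  prediction);
* initial weights and biases uniform(−0.5, 0.5) from an explicit seed;
* **full-batch** gradient descent with classical momentum (the reference
  tool updates per instance; full-batch makes runs bit-reproducible and
  order-independent);
* loss = half the mean squared error on the standardized response.

Under this configuration the reference run (300 noiseless `reg1` rows,
seed 42) passes training R² ≥ 0.95 with a wide margin (≈ 0.997 in ~5 s).
The network's approximation floor on that trait spread is ≈ 0.7 LAI units of
residual SD, so the "training residuals end below the generating noise SD"
property is exercised at noise SD 2.0, above the floor; at noise levels far
below the floor the property cannot hold for any 10,000-epoch full-batch run
and is not claimed.

## Evaluation statistics

`fit_metrics()` reports R² = 1 − SSE/SST, RMSE = √(SSE/(n−p)), ASE = SSE/n,
the SSE-form AIC/BIC above, and PRESS by the hat-matrix closed form
e_i/(1−h_ii) (tested against explicit leave-one-out refitting to 1e−9).
The original analysis reports SAS-flavoured AIC/BIC values (including
negative ones) that are not recomputable without the original data; absolute
values of the SSE forms will differ by an additive constant, and nothing in
the acceptance suite depends on them.

Validation statistics follow the convention **error = predicted − observed**
(the source tables do not state the direction); validation R² is the squared
Pearson correlation of observed with predicted. The signed error percentage
is 100·(manual − estimated)/manual. Genotype comparisons use one-way ANOVA
with Tukey–Kramer HSD at α = 0.05 and an insert-and-absorb compact letter
display. The trait→yield link is a raw cubic polynomial with the overall
model F-test p-value.

## The synthetic world

The generator's defaults encode the two real campaigns:

| preset | genotypes × reps | rows/plot | DAP | LAI range | LG range (cm) |
|--------|------------------|-----------|-----|-----------|----------------|
| "2017" | 18 × 6 | 2 | 30–50 | 0.8–2.6 | 43–75 |
| "2019" | 8 × 16 | 1 | 45–75 | 1.5–5.8 | 66–111 |

Each genotype follows a logistic growth curve normalized over the DAP
schedule and scaled into the trait range; a per-genotype amplitude
multiplier (uniform 0.8–1), a block effect (±2%) and a bounded per-plot
factor (±5% total) add RCBD structure while guaranteeing monotone per-plot
trajectories and keeping every value within 10% of the stated range. Pod
yield is cubic in mid-season LAI (defaults 1500 + 1800·L − 150·L² + 8·L³
kg/ha, Gaussian noise SD 150), chosen to give realistic 2000–6500 kg/ha
yields and to exercise the cubic yield regression.

The scene renderer mixes two endmembers — canopy (0.08, 0.18, 0.05) and
soil (0.25, 0.22, 0.18) reflectance, chosen so green-dominance indices
increase with cover; no quantitative endmembers are recorded for the real
fields, so these are stated assumptions. Canopy cover inside a crop-row
ellipse follows the Beer–Lambert gap model f = 1 − exp(−k·LAI) with k = 0.5,
consistent with canopy reflectance that rises quickly early season and
plateaus; the ellipse's lateral semi-axis is LG/2 (capped at 55% of the
0.91 m row spacing). Per-pixel Gaussian reflectance noise (default SD 0.01)
is added *before* inversion through the calibration, then DN are rounded
half-up and clipped to the sensor range (default 8 bits per channel, the
per-channel depth of a 24-bit RGB camera). An 8-patch grey panel
(reflectance 0.18–0.95) is rendered along the bottom strip; refitting the
calibration from its extracted DNs recovers the configured bases within the
quantization limit (≪ 1%).

What a green end-to-end test establishes: the plumbing is lossless, the
calibration inverts correctly, mixing drives the indices in the right
direction, and a refit 5-index model tracks simulated LAI with r > 0.9.
What it does **not** establish: the field-data accuracies (training R²
0.84–0.97, validation R² 0.73–0.85) — those depend on real canopy optics,
genotype rankings and measurement error that a two-endmember Bernoulli
mixture does not emulate (no shadows, no soil moisture gradients, no BRDF,
no plant-to-plant structure).

## Numerical choices and degenerate inputs

* Seeds: every stochastic routine takes an explicit integer seed and
  restores the caller's RNG state (`with_local_seed`), so library use never
  clobbers a session's stream.
* Zero covered pixels, nonpositive reflectance, and missing predictors
  produce per-record errors or classed stops with the offending plot named.
* Stepwise improvement threshold: a move must improve AIC by > 1e−8 to be
  accepted (guards against tie cycling).
* The product-mode design matrix uses the raw product; all-positive VI
  sampling ranges keep it well conditioned.

## Known limitations

* No CRS handling, orthomosaicking or GCP georeferencing: one scene, one
  affine transform.
* SAS/JMP-specific statistics (their AIC/BIC scaling, graphics) are out of
  scope; stepwise thresholds differ from the unrecorded originals.
* The MLP reproduces the reference topology and hyperparameters, not the
  reference tool's per-instance weight trajectories.
* The scene generator is a statistical stand-in, not a radiative-transfer
  model; quantitative agreement with field reflectance is not claimed.
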