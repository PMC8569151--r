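# aerialpheno

Aerial high-throughput phenotyping of peanut canopy traits from RGB imagery.

Peanut (*Arachis hypogaea* L.) leaf area index (LAI, the ratio of one-sided
leaf area to ground area) and lateral growth (LG, the summed length of the
longest lateral branches on both sides of the main stem, in cm) are strong
proxies for light capture, biomass and pod yield, but measuring them on the
ground — with a ceptometer and a ruler — is slow. This package implements a
complete plot-level pipeline that estimates both traits from UAV-collected
RGB orthomosaics, for breeders and agronomists running replicated field
trials:

1. **Zonal extraction** — mean digital numbers (DN) per plot polygon
   ("fishnet") from three co-registered band rasters.
2. **Empirical-line calibration** — per-band exponential panel calibration
   ρ = a·b^DN fitted by log-linear least squares to an 8-shade reflectance
   panel; the published 2017 and 2019 calibrations are built in.
3. **Vegetation indices** — BGI = B/G, RGR = R/G, NPPR = G/(R+B),
   NGRDI = (G−R)/(G+R), PPR = (G−B)/(G+B), NCPI = (R−B)/(R+B).
4. **Trait models** — the four published frozen estimators
   (`reg1`/`reg2` for LAI, `reg3`/`reg4` for LG, in "sum" and "product"
   form, e.g. LAI = 28.82·BGI + 13.77·PPR − 7.91·NGRDI + 14.88·NCPI +
   25.86·NPPR − 39.74), OLS refitting, AIC forward-backward stepwise
   selection, and a seeded 5-4-3 sigmoid multilayer perceptron
   (lr 0.001, momentum 0.99, 10,000 full-batch epochs).
5. **Evaluation** — R², RMSE, PRESS (closed-form leave-one-out), AIC/BIC,
   ASE, signed error %, validation μ/σ/R², Pearson correlation, paired t,
   one-way ANOVA with Tukey HSD letter groups, and cubic trait→yield
   regression.
6. **Synthetic field trials** — an RCBD trial generator (2017- and
   2019-style presets), a soil/canopy mixture scene renderer with
   Beer–Lambert canopy cover f = 1 − exp(−k·LAI), sensor quantization and a
   rendered calibration panel, so the whole pipeline is testable without
   field data.

Rasters are plain-text ESRI ASCII grids (one per band), fishnets are GeoJSON
FeatureCollections, tables are CSV, and models/calibrations round-trip
through JSON.

## Worked example

```r
library(aerialpheno)

cal <- builtin_calibrations("2017")
refl <- data.frame(plot_id = "G01_r01",
  red   = apply_calibration(95,  cal$red),
  green = apply_calibration(112, cal$green),
  blue  = apply_calibration(68,  cal$blue))
refl
#>   plot_id    red  green   blue
#> 1 G01_r01 0.2986 0.3332 0.2062

vis <- vi_table(refl)
vis[, c("plot_id", vi_names())]
#>   plot_id    bgi    rgr   nppr   ngrdi    ppr   ncpi
#> 1 G01_r01 0.6187 0.8962 0.6601 0.05474 0.2355 0.1832

as.numeric(estimate_trait(vis, frozen_model("reg1")))  # 0.698
as.numeric(estimate_trait(vis, frozen_model("reg2")))  # 0.622
```

A plot whose mean DNs are (95, 112, 68) calibrates to a fairly soil-like
reflectance triple; both LAI estimators agree on a sparse canopy (LAI ≈ 0.6–0.7,
i.e. very early season). The full pipeline — simulate a campaign, extract,
calibrate, index, estimate, evaluate — is wired together by
`simulate_campaign()`, `run_estimation()` and `run_validation()`, or from a
shell via `inst/cli/aerialpheno.R` (subcommands `simulate`, `extract`,
`calibrate`, `indices`, `estimate`, `validate`).

## Limitations

Raw field data from the original trials are not public, so the package's
tests establish *self-consistency* (every printed constant is recovered from
data its own frozen models generate) and *pipeline correctness* on synthetic
scenes — not the field-data accuracies. See the methods vignette
(`vignettes/aerialpheno-methods.Rmd`) for the model assumptions, generator
design and known limitations.
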