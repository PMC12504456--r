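# coinvade

Predicting occurrence and **co-invasion** of two invasive Asteraceae plant
genera — an *Erigeron*-like early ruderal (genus E) and a *Solidago*-like
perennial (genus S) — in heterogeneous post-industrial landscapes, from
fused field and multi-resolution remote-sensing data.

The package is aimed at spatial ecologists and invasion biologists who have
presence–absence plot records plus co-registered raster predictors and want
a tested, reusable pipeline from raw layers to co-invasion maps. Because
the real field campaign and imagery archives cannot ship with a package,
`coinvade` includes a first-class synthetic landscape generator with known
niche structure, so every stage is verifiable end to end.

## What it computes

**Predictors.** Plot-level field-data features: species counts (all /
native), Functional Richness as the convex-hull volume in pool-standardized
trait space (FRic, with random-forest imputation of degenerate hulls),
community-weighted mean SLA, seed mass and maximal height, and a succession
gradient as the first NMDS axis of the presence–absence community table.
Remote-sensing features at native resolutions: 5-m canopy-height focal
statistics (CHMmean, CHMsd), 30-m multi-temporal composites

```
NDVI = (NIR − Red) / (NIR + Red)        (per-pixel min composite of bands first)
LST  = scale · DN + offset − 273.15     (per-pixel max composite, °C)
```

seven reflectance bands (10/20/60 m), disturbance-index focal mean/sd
(TCDImean, TCDIsd), focal-minimum leaf-area proxy (SeLImin), and
moving-window Rao's quadratic entropy

```
Q = Σᵢ Σⱼ dᵢⱼ pᵢ pⱼ,   pᵢ = 1/N,  dᵢⱼ = |vᵢ − vⱼ|
```

on NDVI and on NIRv = NDVI × NIR.

**Models.** Per genus: stratified 75/25 split, then gradient boosting,
radial-kernel SVM or random forest tuned by AUC under 10×10 repeated
stratified cross-validation; evaluation by sensitivity, specificity,
precision, F1, accuracy (from the held-out confusion matrix) and AUC ± its
cross-validation SD; scaled variable importance and partial dependence.

**Ordination.** Redundancy analysis of the two predicted occurrence
probabilities on the fused predictors (type-2 scaling scores) with
VIF-based redundancy screening (VIF > 10).

**Maps.** Final full-data models predict every 5-m pixel; each genus is
binarized at the threshold minimizing |sensitivity − specificity| over the
cross-validation records (mean over resamples of the best of 100 candidates
0.01…1.00); the co-invasion layer is the intersection of the two masks,
accounted in hectares, site percentages, broad land-cover classes, and
Welch-t / Cohen's-d contrasts of key predictors between the genera.

## Worked example

```r
library(coinvade)

cfg <- scene_config(extent = 300, seed = 42)   # 300-m synthetic scene
run <- run_pipeline(cfg, k = 5, repeats = 4, nmds_restarts = 5)

run$final$models$E
#> <trained_model> GBM | n = 358, p = 16 | CV AUC 0.870 (+- 0.027)
#> tuned: n.trees = 100, interaction.depth = 3

round(run$evaluation$E$fused$metrics, 3)
#> sensitivity specificity   precision          f1    accuracy
#>       0.706       0.964       0.923       0.800       0.865

round(run$final$thresholds, 3)
#>     E     S
#> 0.405 0.414

run$final$coverage
#>      category pixels hectares percent
#> 1           E   1620     4.05    45.0
#> 2           S   1588     3.97    44.1
#> 3 co_invasion    696     1.74    19.3
```

Reading the output: the final genus-E gradient-boosting model separates
presences from absences with cross-validated AUC 0.87; on the held-out
quarter of the plots it recovers 70.6% of presences (sensitivity) while
keeping 96.4% of absences (specificity). The balanced probability
thresholds (0.405 / 0.414) binarize the 5-m suitability surfaces: 45.0% of
the scene is suitable for genus E, 44.1% for genus S, and 19.3% for both at
once — the co-invasion area, never exceeding either genus alone. The niche
contrast behind the maps:

```r
run$final$contrasts$LST[c("mean_a", "mean_b", "cohens_d")]
#> E pixels average 36.7 °C vs 34.6 °C for S (Cohen's d = 0.85):
#> genus E occupies hotter, more open ground
run$final$contrasts$CHMmean[c("mean_a", "mean_b", "cohens_d")]
#> E 4.13 m vs S 8.17 m mean canopy height (d = -0.98):
#> genus S tolerates taller vegetation
```

## Package layout

- `R/synthgen.R` — synthetic landscape generator (latent fields, bands,
  occupancy truth, plot sampling)
- `R/raster.R`, `R/rsfeat.R` — raster grid container, focal/composite/
  Rao's Q operators, layer derivation and point extraction
- `R/fieldfeat.R` — counts, CWM, FRic (convex hulls), imputation, NMDS
  succession axis
- `R/classify.R` — partitioning, repeated CV, AUC tuning, metrics,
  importance, partial dependence
- `R/ordinate.R` — RDA wrapper and VIFs
- `R/mapping.R` — thresholds, suitability/co-invasion maps, land-cover
  accounting, contrasts
- `R/pipeline.R` — the end-to-end driver
- `vignettes/coinvasion-workflow.Rmd` — the methods vignette (models,
  assumptions, design choices, limitations)
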