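---
title: "Modelling occurrence and co-invasion of two invasive plant genera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling occurrence and co-invasion of two invasive plant genera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coinvade` implements a complete workflow for predicting where two invasive
Asteraceae genera — an *Erigeron*-like early ruderal ("genus E") and a
*Solidago*-like perennial ("genus S") — occur, and where they co-occur, in
heterogeneous post-industrial landscapes. The workflow fuses plot-level
field data with multi-resolution remote sensing, trains presence-absence
classifiers, links the two predictor families by canonical ordination, and
turns the fitted models into pixel-based suitability, binary and
co-invasion maps. This vignette explains the models and the design choices;
the README shows a worked example.

## The modelling problem

The observational unit is a small circular vegetation plot (28.3 m², i.e. a
3-m radius) with per-species cover estimates and a presence/absence label
per genus. Around the plots sits a stack of co-registered rasters at their
native resolutions: a 1-m LiDAR canopy height model, 30-m multi-temporal
Red/NIR/thermal imagery, 10/20/60-m reflectance bands, a 10-m disturbance
index (TCDI), a 10-m leaf-area proxy (SeLI) and a 10-m land-cover
classification. The tasks are:

1. **Classification** — model each genus's presence from (a) fused field +
   remote-sensing predictors and (b) remote-sensing predictors alone, with
   three learners (stochastic gradient boosting, radial-kernel SVM, random
   forest) tuned by AUC under 10-fold cross-validation repeated 10 times
   after a stratified 75/25 train/test split.
2. **Ordination** — redundancy analysis (RDA) of the two predicted
   occurrence probabilities on the fused explanatory matrix, with variance
   inflation factors flagging redundant predictors (VIF > 10).
3. **Mapping** — refit the chosen learner on all plots with the
   remote-sensing predictors, pick a per-genus probability threshold that
   balances sensitivity and specificity over the cross-validation records,
   predict every 5-m pixel, binarize, intersect the two masks into a
   co-invasion layer, and account for the result in hectares, site
   percentages, broad land-cover classes and group contrasts.

## The synthetic landscape generator

Real field campaigns and imagery archives cannot be shipped with a package,
so every stage is exercised against `scene_config()` /
`generate_scene()`, a generator with *known* niche structure. Its defaults
are the study conditions: a square scene whose edge divides by 60 m (all
grids nest exactly), ten acquisition dates, 358 plots of 28.3 m², a target
spatial prevalence of 0.40 per genus, and overlapping niches that yield
roughly 20% joint prevalence.

**Latent fields.** Five spatially autocorrelated fields are built by
smoothing Gaussian white noise on the 1-m master grid with a Gaussian
kernel (bandwidth 20 m by default; the smoother is a pair of row/column
band matrices with row-normalized truncated kernels, so the operation is
exactly linear and edge-safe). Height is a logistic transform of one
smoothed field (0–25 m, skewed low); succession is by construction a
strictly monotone transform of the same field (succession builds tall
vegetation); temperature cools under tall canopy; disturbance concentrates
where succession is young; moisture varies independently with a slight
anti-correlation to temperature. A derived `biomass` field in [0, 1]
(monotone in moisture and succession) drives the optical bands.

**Bands.** Each sensor product is an affine function of the aggregated
latents plus Gaussian noise, clamped to [0, 1] for reflectances: NIR rises
with biomass, Red and SWIR1 fall with biomass and moisture respectively,
the thermal band encodes temperature through the producer's inverse scaling
(so the pipeline's Kelvin conversion is exercised honestly). Dates after
the first may carry smooth "cloud" blobs that brighten Red/NIR and cool the
thermal band — exactly the artifact the per-pixel min (optical) and max
(thermal) composites are meant to remove; keeping date one clean guarantees
the composite recovers the clean signal. Land cover comes from
deterministic thresholds on the latents (tall = trees, mid = shrub, sparse
biomass = bare, high disturbance = built, very wet and low = water).

**Truth and plots.** Each genus's occupancy probability is a logistic niche
on the standardized latents — genus E: hot, low, disturbed,
early-successional; genus S: moist, disturbed, peaked at intermediate
succession (both genera share the ruderal affinity for disturbance, which
is what creates the ~20% joint prevalence through niche overlap rather
than an explicit coupling). The intercept is calibrated by bisection so the
spatial mean probability hits the target prevalence to better than 0.001;
occupancy is an independent Bernoulli draw per genus given the landscape.
Plot labels are read from the occupancy draw at the plot pixel. Native
richness rises with succession and falls slightly on invaded plots (the
`fd_signal` knob); species are drawn by succession affinity from a 60-species
pool whose height trait grows with that affinity — so composition turns
over along the gradient (recoverable by NMDS) and community-weighted height
tracks the height field. Because richness responds to the *realized*
occupancy draw, part of the label signal travels exclusively through the
field features, which is why fused models outperform remote-sensing-only
models on synthetic scenes, mirroring the drop observed with real data.

**What the generator does not emulate:** radiative transfer, phenology,
sensor geometry, spatial autocorrelation of species composition beyond the
latent gradients, observer error in cover estimates, and spatially
clustered (rather than independent) occupancy. Passing tests therefore
demonstrate correctness of the machinery and recoverability of a known
niche structure — not field-level realism.

## Field-data features

* **Counts** (`species_counts()`): species with positive cover, all vs
  native.
* **Community-weighted means** (`cwm()`): cover-weighted trait averages;
  species missing a trait are dropped from that combination; an empty
  community yields a missing value that flows to imputation.
* **Functional Richness** (`fric()`): convex-hull volume in trait space
  (SLA, seed mass, maximal height) standardized over the *full species
  pool*, not per plot — hull volumes are then comparable across plots and
  invariant to raw trait units. With s species and t traits the hull is
  computed in min(t, s − 1) dimensions, projecting onto leading principal
  axes when s ≤ t (the axis reduction used by the standard dbFD-style
  implementations); fewer than two species or a rank-deficient point set is
  missing, not an error. The 3-D hull volume applies a deterministic
  micro-jitter (10⁻⁹ of the coordinate range) to reach general position and
  then enumerates boundary facets exactly; volumes are exact to ~10⁻⁶.
* **Imputation** (`impute_fric()`): missing FRic values (degenerate hulls)
  are filled by a random-forest regression on the remaining FD1 variables
  plus the auxiliary leaf-dry-matter-content CWM (used for imputation
  only), reporting out-of-bag R². Tree ensembles cannot extrapolate, so
  imputed values stay inside the observed range.
* **Succession axis** (`succession_axis()`): 2-D NMDS on Bray–Curtis
  (= Sørensen) distances of the presence-absence community table, best of
  20 random restarts by stress (a config knob); axis 1 is the gradient,
  with its sign fixed so the score rises with community-weighted height.

## Remote-sensing features

`rs_layers()` derives the 16 predictor layers. Numerical conventions that
matter:

* **Compositing order**: the Red and NIR date stacks are composited first
  (per-pixel minimum) and NDVI is computed from the composites — not
  per-date NDVI then composite; the two differ and the former is
  implemented. Thermal uses the per-pixel maximum (yearly extreme heat),
  then °C = 0.00341802 · DN + 149.0 − 273.15 with both constants
  overridable (the default pair is the Landsat Collection-2 producer
  constants).
* **Focal statistics**: 5 × 5 windows, truncated at edges (no padding),
  n − 1 denominator for the standard deviation, a pixel missing only when
  the whole window is missing. The 1-m canopy model is aggregated to 5 m by
  exact block statistics, which equals evaluating the 5 × 5 focal at the
  5-m cell centers; the alternative (focal then nearest-neighbour resample)
  differs only at nodata edges.
* **Rao's Q**: equal weights `p_i = 1/N` over the N valid window cells and
  absolute-difference distances, normalized by N² including the zero i = j
  terms — the spectral formulation of quadratic entropy. Q is computed on
  the 30-m composite NDVI and on a 10-m NIRv (the product of the 10-m
  Sentinel-like NDVI and NIR bands); which NDVI feeds Rao's Q was an open
  design point, resolved in favour of the 30-m composite for `RaoQ_NDVI`.
* **Extraction**: the value of the cell containing the point, no
  interpolation, cells as half-open intervals anchored at the grid's
  top-left corner. Plot-level extraction uses the plot center (disc
  averaging over the 28.3 m² plot would mix at most a handful of 1-m cells
  and none at coarser grids).

## Classification

The learners are the field-standard engines — random forest
(`randomForest`), radial-kernel SVM (`kernlab`, with Platt-type probability
calibration and internal centering/scaling, which only the SVM needs) and
stochastic gradient boosting on the xgboost engine with the classical
boosting surface: number of trees and interaction depth tuned, learning
rate fixed at 0.1, minimum terminal-node size fixed at 20 observations
(mapped to a hessian weight of 5 under the logistic loss, since the
logistic hessian contributes ≈ 0.25 per observation), and half-sampling per
iteration. Everything around the engines is implemented in the package:
stratified partitioning (per-class ceiling for the training count — a
75/25 split of 358 observations with 143 presences gives the canonical
88-observation test set), repeated stratified folds, the AUC-maximizing
grid search (same folds for every candidate; ties resolved toward the
first, least complex, candidate), rank-based AUC with midrank tie
correction, confusion-matrix metrics with undefined-not-zero semantics for
empty denominators, min-max-scaled importance (learner-native: gain for
boosting, impurity decrease for the forest, a per-variable separation-AUC
filter for the SVM), and partial dependence in probability mode. One
experiment seed governs partition, folds and learner randomness through
fixed sub-seeding.

Default tuning grids (all overridable): boosting trees 50–500 by 50 ×
depth 1–3; forest `mtry` spread over 1…p; SVM sigma from the median
heuristic band × cost 0.25–4. The shipped pipeline and acceptance runs use
a compact boosting grid (trees 100/200 × depth 2/3) — with 16–27
predictors and a few hundred plots the AUC surface is flat over the wider
grid, and the compact grid keeps a full pipeline run around a minute.

## Ordination

`rda_probs()` regresses the centered probability matrix on the explanatory
matrix and eigen-decomposes the fitted values (engine: `vegan::rda`).
Explanatory columns are standardized to unit variance — field and
remote-sensing variables differ by orders of magnitude in scale, and VIFs
are scale-free so nothing is lost. Scores are reported in type-2 scaling
(correlation biplot); because "type 2" alone underdetermines constants,
the package simply adopts the `vegan` convention. VIFs are computed from
first principles (1/(1 − R²) per column) with exact collinearity reported
as infinite; the screening rule flags VIF > 10.

## Thresholds, maps and accounting

`select_threshold()` scans exactly the 100 candidates 0.01…1.00 per
cross-validation resample, minimizes |sensitivity − specificity| and takes
the smallest qualifying threshold on ties (conservative toward
sensitivity); the genus threshold is the mean over resamples. Thresholding
is per genus on that genus's labels — the only reading under which two
distinct genus thresholds exist; a joint-label variant would collapse both
genera onto one labelling and was rejected. Classification at the
model-comparison stage stays at probability 0.5; the balanced thresholds
belong to the mapping stage only.

`predict_map()` rasterizes per-landmark probabilities back to the 5-m
grid, binarizes at the genus thresholds (positive when probability ≥
threshold) and intersects the masks; a pixel missing any feature is nodata
everywhere. Coverage converts 25-m² pixels to hectares; with no explicit
site area the valid-pixel area is used, which makes the
E-only/S-only/co-invaded/neither accounting close exactly. Land cover is
reduced to four broad classes (high vegetation; low vegetation = grass,
crops, shrub and flooded vegetation; bare ground; built area) with water
kept as its own class and snow/ice excluded; unknown codes are loud
errors. Group contrasts use the two-sided Welch t-test and Cohen's d with
the pooled standard deviation, positive d meaning the genus-E mean is
larger; rounding to presentation precision happens only in reports, never
in stored values.

## Numerical choices and degenerate inputs

* Intercept calibration: bisection on [−25, 25], 80 iterations, unreachable
  prevalence is an error.
* Hull degeneracy: rank via singular values with a 10⁻⁸ relative cut.
* Folds whose held-out part would be single-class are regenerated under a
  new sub-seed (only possible when a class has fewer members than folds);
  single-class resamples are skipped in threshold selection with a warning.
* Zero denominators (metrics, NDVI, CWM, Rao's Q windows with < 2 valid
  cells) yield missing values, not exceptions; genuinely contradictory
  inputs (non-nesting grids, unknown class codes, constant RDA responses)
  are errors.
* Rasters serialize as ESRI ASCII grids — a plain-text, GIS-readable
  exchange format — plus CSV plot tables.

## Problem sizes

The shipped configuration uses a 600-m scene (360 000 1-m cells, 14 400
5-m landmark pixels), 358 plots, 10 × 10 cross-validation, the compact
boosting grid, and 10–20 NMDS restarts. A full pipeline run (generation,
features, six tuned models, ordination, thresholds, map, accounting)
completes in about a minute on one core; all sizes scale up through
`scene_config()` and the pipeline arguments.

## Limitations

Spatial cross-validation is not implemented (folds ignore plot location, so
spatial autocorrelation can flatter the CV AUC on real data); uncertainty
is summarized only as the cross-validation AUC standard deviation; the
ordination offers no permutation significance test; and the generator's
independence assumptions (occupancy draws, band noise) make the synthetic
benchmark easier than field reality in ways the tests deliberately do not
hide.
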