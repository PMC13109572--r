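---
title: "Voxel-based canopy fPAR mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based canopy fPAR mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxfpar)
```

## The problem

Nadir-view multispectral imagery sees only the uppermost illuminated canopy
surface, while quantum sensors measure the fraction of absorbed
photosynthetically active radiation (fPAR) at a handful of discrete heights
per tree. voxfpar bridges the two: it distributes top-of-canopy reflectance
through a LiDAR-derived 3-D canopy structure, attaches stratum-level fPAR
labels from six-component PAR balances, trains a regressor on
vegetation-index predictors, and reads the resulting voxel field back out as
vertical profiles, stratum contrasts and family-level statistics. The
voxel-scale output is therefore a *structurally guided redistribution of
stratum-level fPAR*, not an independent optical retrieval for every interior
voxel — nadir sensors cannot measure interior reflectance, and the package
does not pretend otherwise.

## Radiative model

The six sensor components per tree are incident (i) and reflected (r) PAR at
the canopy top (c), mid-canopy (m) and base (g). Two balances are available
in `compute_apar_fpar()`:

* `three_layer` (default): `APAR = PAR_ci − PAR_cr − (PAR_gi − PAR_gr) −
  (PAR_mi − PAR_mr)`. This verbatim three-layer form subtracts both the
  middle and ground net fluxes from the top net flux; when much of the
  incident flux passes through unabsorbed it can drive fPAR negative (the
  extreme pass-through case yields fPAR = −1). Such records are *flagged
  invalid, never clipped*, so the verbatim balance remains reproducible
  while its pathology stays visible.
* `two_layer`: `APAR = (PAR_ci − PAR_cr) − (PAR_gi − PAR_gr)`, the
  physically consistent whole-canopy balance, always in [0, 1] for ordered
  components.

How one balance splits into three per-stratum values is genuinely open; the
package's documented choice (`compute_layer_fpar()`) differences net
downward fluxes: with `Φ_c = PAR_ci − PAR_cr` etc.,

```
upper  = (Φ_c − Φ_m) / PAR_ci
middle = (Φ_m − Φ_g) / PAR_ci
lower  = Φ_g · (1 − τ_floor) / PAR_ci
```

`τ_floor` (default 0) is the assumed transmission through the lowest layer
to the forest floor; with the default, all flux reaching the base sensor is
attributed to the lower layer, so the three fractions sum to the two-layer
whole-canopy fPAR. The simulator's forward model uses exactly this
decomposition, and the test suite verifies that feeding noiseless,
albedo-free simulated components back through `compute_layer_fpar()`
reproduces the true layer absorption to 1e-9 — a closed loop, not a
validation against field data.

## Vegetation-index registry

The published index table this registry transcribes is typographically
corrupted in places: its NDRE is printed as a bare difference, its ARI is
printed identically to GNDVI, and the RECI/MARI denominator is ambiguous
between "red minus red edge" and the red-edge band. `compute_index()`
therefore ships two variants:

* `canonical` (default): NDRE = (NIR − RE)/(NIR + RE), ARI = 1/G − 1/RE,
  and RECI/MARI read the denominator as the 730 nm band (RECI = NIR/RE − 1,
  MARI = NIR/RE).
* `as_printed`: the printed text evaluated verbatim where it parses
  (NDRE = NIR − R − RE; ARI duplicates GNDVI; RECI/MARI divide by R − RE).

GCI, LCI, GRVI, MGRVI and MACI keep their printed formulas in both variants
even though some differ from the indices usually published under those
names; `vi_registry()` exports the exact formula strings so there is no
ambiguity about what was computed. Zero denominators yield missing values,
and rows with missing predictors are dropped from model fitting (with a
recorded count) rather than imputed.

## Fusion rules and numerical choices

* **Binning** is always half-open and lower-edge inclusive, with the grid
  origin snapped to `floor(min/cell)·cell`; no point can be counted twice.
* **Column top**: the highest normalized point per column; ties resolve to
  the smallest point index. Reflectance is sampled by nearest neighbour —
  the fusion assigns "the pixel at that location", not an interpolation.
* **Segmentation** ties (plateau maxima, equidistant markers) resolve to
  the lexicographically smallest cell; determinism is preferred over
  elegance, and byte-identical reruns are part of the test contract.
* **Stratum thresholds**: fixed 15 m / 7 m by default, matching the
  published zoning for a ~18 m canopy. Percentile-derived thresholds
  (75th/40th, linear-interpolation quantiles) are available but degenerate
  on even-aged stands whose height spread is small — on such stands both
  percentiles land within a metre of each other, which is why `fixed` is
  the default. Voxel height for all stratum tests is the bin centroid
  `(k + 0.5)·dz`.
* **Resolutions**: the field-scale 0.01 m × 0.01 m × 2 m voxel grid is
  admissible through the configuration, but the desk-scale default is
  0.25 m horizontal — the package is exercised end-to-end on stands of
  20–80 trees (~10⁴–10⁵ points, ~10⁴ voxels), which one CPU handles in
  seconds.
* **Predictions** are clipped to [0, 1] with a `clipped` flag; missing
  predictors give missing predictions, never silent zeros.

## Model protocol

Training rows are tree × stratum aggregates: index predictors averaged over
a tree's voxels in each stratum, labelled with that tree's stratum fPAR.
Calibration/validation splits (80/20) and all cross-validation folds are
grouped by tree, so no tree ever straddles a split — the grouping mitigates
the spatial leakage that plagues voxel-level splits. Predictors are
standardized (calibration statistics only) for SVM and PLSR; tree ensembles
consume raw indices. Grid search, when enabled, minimizes mean grouped-CV
RMSE over small documented grids centred on the default hyperparameters
(RF mtry {4, 6, 8}; SVM C {1, 10, 100} × γ {0.01, 0.1, 1}; XGBoost
η {0.01, 0.05} × depth {4, 6}; PLSR 4–10 components). Variable importance
is permutation-based: the mean RMSE increase when one predictor column is
shuffled, the model-agnostic analogue of mean decrease in accuracy. With
collinear predictors, importance mass splits across the collinear set —
the test suite asserts this behaviour rather than hiding it.

## What the simulator emulates — and what it does not

`stand_config()` defaults describe the study conditions: a gridded
plantation of 6 m × 8 m spacing, 20 half-sib families in randomized blocks,
canopy height 18 ± 1 m, crown radius 0.15·height, LAI 5 m²/m², extinction
coefficient k = 0.7, quantum sensors at 20/10/4 m, albedo 0.05 per level,
multiplicative PAR noise 5 %. Crowns are right circular cones (apex at tree
height, base at the ground) with vertically uniform leaf-area density, so
cumulative leaf area above height z is `L(z) = LAI·(h − z)/h` and every
absorbed fraction has a closed form. The k·LAI product of the defaults was
chosen so that per-layer absorbed fractions decrease monotonically from the
upper to the lower stratum; the gradient-recovery analysis instead uses
k·LAI = 1.335, the closed-form solution for a 26 % lower→upper increase at
h = 18 m.

Reflectance is a one-parameter family: each crown pixel takes a five-band
foliage spectrum driven by *effective chlorophyll*, the tree's chlorophyll
level scaled by relative canopy-surface height (`0.15 + 0.85·z_surf/h`) —
sunlit apex foliage expresses more chlorophyll than shaded crown edges, so
red-edge indices rise toward the crown top and carry the vertical signal.
Family chlorophyll means are drawn from a narrow band (0.45–0.55, tree-level
noise 0.02): within-species chlorophyll variation is small relative to the
canopy-surface gradient. A per-tree visible-band brightness factor
(log-normal, σ = 0.10) perturbs only the 450/560/650 nm bands, emulating
illumination and background variation that contaminates broadband indices
while leaving the red-edge/NIR pair clean — which is why red-edge indices
dominate importance rankings in the recovery tests. Tree LAI increases
monotonically with chlorophyll (`LAI_mean·(0.85 + 0.3·chl)`), closing the
reflectance→fPAR coupling.

The simulator is deliberately not a radiative-transfer model: no BRDF, no
multiple scattering, no occlusion between crowns beyond the highest-surface
rule, no within-crown gap structure, no phenology beyond a date label.
Passing tests therefore demonstrate that the *pipeline machinery* —
discretization, fusion, labelling, learning, statistics — is correct and
recovers planted signal under the stated noise, not that any particular
field accuracy will be achieved on real imagery, where shadowing, BRDF
effects and sensor calibration dominate the error budget.

## Statistics

One-way ANOVA uses the standard between/within decomposition (via `lm`);
zero within-group variance with unequal means reports an infinite F and
p = 0 explicitly. Duncan's multiple range test sorts means descending and
applies the stepwise range procedure: a span of p means is non-significant
when its extreme difference falls inside
`q((1−α)^(p−1), p, df₂)·√(MS_within/n_h)` (studentized-range quantile from
base R, harmonic-mean group size for unequal n), and no span inside a
non-significant span may be declared significant. Letters are assigned to
maximal non-significant runs; the suite checks letter-sharing against a
direct enumeration of all containing spans on 3–6-group fixtures. Monthly
aggregation keeps gaps as explicit missing values; nothing is interpolated.

## Known limitations

* Column-constant reflectance bounds what any regressor can resolve
  vertically: two voxels of one column differ only through their stratum
  context, so vertical discrimination rests entirely on which columns
  contribute to which stratum.
* The three-layer balance can label a tree with invalid fPAR; downstream
  stages use the layered decomposition, and invalid records are the
  caller's to filter (they stay flagged).
* Percentile thresholds assume a height distribution with usable spread
  (see above).
* The greedy nearest-apex tree matcher assumes stem maps and apexes agree
  to ~3 m; heavily overlapping crowns need a better matcher than this
  package provides.
* `read_las`/`write_las` implement the minimal LAS 1.2 point-format-0
  subset the pipeline needs (coordinates, classification, return number) —
  they are a codec, not a general LAS toolkit; rasters travel as float
  TIFF with world-file plus scaling sidecars.
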