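# voxfpar

Three-dimensional mapping of the fraction of absorbed photosynthetically
active radiation (fPAR) through conifer canopies, by fusing UAV LiDAR point
clouds with five-band multispectral orthomosaics. The package is aimed at
forest remote-sensing and tree-breeding groups who fly LiDAR and
multispectral sensors over plantation trials, measure PAR with quantum
sensors on poles, and want voxel-resolved fPAR fields plus the statistics
(vertical profiles, stratum contrasts, family ANOVA) that follow from them.

## Method

The workflow chains six stages around one regression model:

1. **LiDAR processing.** Ground returns are classified per grid cell
   (minimum + tolerance), heights are normalized against a bilinearly
   interpolated terrain model, a canopy height model (CHM) is rasterized as
   the per-cell maximum, and individual trees are segmented by
   marker-controlled watershed on the inverted, Gaussian-smoothed CHM.
2. **Fusion.** The normalized cloud is voxelized into vertical columns
   (`i = ⌊(x−x₀)/dx⌋`, `k = ⌊z/dz⌋`). For each column the highest LiDAR
   point is located, the orthomosaic pixel at that horizontal position is
   sampled (nearest neighbour, after an affine co-registration fitted to
   ground-control pairs), and its five-band reflectance is duplicated to
   every occupied voxel of the column — reflectance is constant within a
   column, varying only across the observed canopy surface.
3. **Vegetation indices.** Fourteen indices (NDVI, OSAVI, GNDVI, SAVI,
   MSAVI, GCI, RECI, LCI, GRVI, MGRVI, NDRE, MACI, ARI, MARI) are evaluated
   on the band set 450/560/650/730/840 nm, e.g.
   `NDVI = (R₈₄₀ − R₆₅₀)/(R₈₄₀ + R₆₅₀)` and `RECI = R₈₄₀/R₇₃₀ − 1`.
4. **Ground truth.** Six quantum-sensor components per tree (incident and
   reflected PAR at canopy top, mid-canopy and base, averaged over four
   cardinal directions) become absorbed PAR via the three-layer balance
   `APAR = PAR_ci − PAR_cr − (PAR_gi − PAR_gr) − (PAR_mi − PAR_mr)` and
   `fPAR = APAR / PAR_ci`; per-stratum fPAR labels are assigned to voxels
   by height zone (upper ≥ 15 m, 7 m ≤ middle < 15 m, lower < 7 m, or
   percentiles of segmented tree heights).
5. **Regression.** `fpar_train()` fits RF (300 trees, mtry 6), XGBoost
   (η = 0.01, 500 rounds, depth 6), RBF-SVM (C = 10, γ = 0.1) or PLSR
   (10 components) to tree × stratum rows of stratum-averaged indices,
   under tree-grouped repeated 10-fold cross-validation with optional grid
   search; skill is `R² = 1 − Σ(yᵢ−ŷᵢ)²/Σ(yᵢ−ȳ)²` and
   `RMSE = √(Σ(yᵢ−ŷᵢ)²/n)`. Voxel predictions are clipped to [0, 1].
6. **Statistics.** Vertical profiles in 5 m bins, lower→upper gradients
   (`100·(f̄_upper − f̄_lower)/f̄_lower`), tree/stratum/family aggregates,
   one-way ANOVA and Duncan's multiple range test with studentized-range
   critical values.

A synthetic plantation simulator (`generate_stand()`, `sample_point_cloud()`,
`render_orthomosaic()`, `simulate_par()`) provides cone crowns, Beer–Lambert
light extinction `PAR(z) = PAR₀·exp(−k·L(z))` and a reflectance model coupled
to chlorophyll, so every stage is testable against known ground truth. See
the methods vignette (`vignettes/canopy-fpar-mapping.Rmd`) for the model
assumptions and design choices.

## Worked example

```r
library(voxfpar)
cfg <- run_config(out_dir = file.path(tempdir(), "demo"), seed = 42)
run_pipeline(cfg)   # simulate → fuse → indices → label → train → predict → profile → stats
read.csv(file.path(cfg$out_dir, "metrics.csv"))
#>           set        r2       rmse  n
#> 1 calibration 0.9982440 0.01291281 48
#> 2  validation 0.9975828 0.01507984 12
read.csv(file.path(cfg$out_dir, "duncan_layers.csv"))
#>    group       mean  n letters
#> 1  upper 0.69059056 20       a
#> 2 middle 0.25357783 20       b
#> 3  lower 0.09209463 21       c
read.csv(file.path(cfg$out_dir, "profile.csv"))
#>   bin_low bin_high       mean count
#> 1       0        5 0.07760031  4223
#> 2       5       10 0.15512878  4056
#> 3      10       15 0.39647563  1195
#> 4      15       20 0.68669358   436
```

The metrics table reports calibration and held-out tree skill of the default
random-forest model on the simulated 20-tree demo stand. The Duncan table
says the three canopy layers differ significantly (no shared letters), with
mean voxel fPAR falling from 0.69 (upper) to 0.09 (lower); the profile shows
the same attenuation in 5 m height bins. Each stage writes a YAML manifest
(config hash, input hashes, seed), and re-running a stage with unchanged
inputs reproduces its CSV outputs byte for byte.

A thin command-line wrapper ships in `inst/cli/fparpipe.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "fparpipe.R", package = "voxfpar"))')" \
  --stage all --out runs/demo --seed 1
```

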