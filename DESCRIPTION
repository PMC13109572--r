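Package: voxfpar
Title: Voxel-Based Canopy fPAR Mapping from Fused UAV LiDAR and Multispectral Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping the fraction of absorbed photosynthetically
    active radiation (fPAR) in three dimensions through conifer canopies by
    fusing UAV LiDAR point clouds with five-band multispectral orthomosaics.
    The package normalizes and segments point clouds, voxelizes canopies into
    vertical columns, propagates top-of-canopy reflectance down each column,
    computes a registry of fourteen vegetation indices, converts six-component
    quantum-sensor readings into stratum-level fPAR labels, fits and compares
    four regressors (random forest, gradient boosting, support vector
    regression, partial least squares) under tree-grouped cross-validation,
    and summarizes the resulting fPAR fields by height bin, canopy stratum,
    family and month, including one-way ANOVA with Duncan's multiple range
    test. A synthetic plantation simulator with known geometry, reflectance
    and Beer-Lambert light extinction provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    data.table,
    tiff,
    yaml,
    randomForest,
    e1071,
    xgboost,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
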