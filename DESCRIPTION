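Package: stacksdm
Title: Stacked Species-Distribution Modeling, Range Shifts, and Protected-Area Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for stacked species-distribution modeling on gridded
    environmental covariates: occurrence cleaning, spatial thinning and k-fold
    partitioning; collinearity screening and climate-ensemble averaging;
    maximum-entropy presence-background niche models with linear, quadratic,
    product, threshold and hinge features; threshold-free and maxTSS-thresholded
    evaluation; model transfer to future climates with mobility-oriented parity
    extrapolation detection and occurrence-based restriction; binary-map
    stacking into species richness, per-species range-shift statistics, and a
    richness-change by vegetation-change prioritization of protected areas.
    Includes a synthetic virtual-species world generator so the whole pipeline
    is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
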