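Package: sargassdm
Title: Presence-Background Distribution Modelling of Canopy-Forming
    Macroalgae Under Climate Scenarios
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable, tested pipeline for presence-only species
    distribution modelling of coastal canopy-forming macroalgae
    (Sargassum) on gridded marine environmental layers. Implements a
    from-scratch maximum-entropy (MaxEnt) presence-background model with
    linear, quadratic and hinge features and L1 regularization; variable
    screening by permutation contribution, pairwise correlation and
    variance inflation factors; beta-multiplier tuning by replicate test
    AUC; projection of habitat suitability to climate-scenario layers
    (SSP pathways and future periods); block-averaged habitat
    suitability classification; and range-change analytics (change
    categories, suitable-habitat area, HSI-weighted latitudinal
    centroids, multi-species richness, and marine-protected-area
    overlap). A synthetic-data module generates spatially autocorrelated
    environmental layers, bathymetry-based depth masks, occurrence
    records sampled from a known suitability surface, and polygonal MPA
    masks so the whole pipeline is testable without external data.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    sp,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
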