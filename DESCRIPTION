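Package: phenocast
Title: Plot-Level Crop Biomass Prediction from Multimodal Phenotyping Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-of-season fresh biomass prediction for sorghum breeding
    trials from time-series UAV remote sensing (hyperspectral and LiDAR),
    daily weather, and genome-wide marker data. Provides a synthetic
    breeding-trial simulator, plot-level feature extraction (vegetation
    indices, spectral integration and derivative features, canopy height
    percentiles and cover, cumulative thermal time), PCA-loading feature
    importance with majority-vote pruning across trials, marker-based
    genotype clustering with elbow selection of k, a stacked-LSTM recurrent
    regressor with static genotype-cluster inputs trained by Adam, and two
    transfer-learning sample-selection strategies (genomic and phenotype)
    for fine-tuning across trial domains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
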