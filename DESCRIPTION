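Package: bamscope
Title: Brain Activity Map Screening and Functional Drug Prediction in Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for phenotypic drug screening from whole-brain calcium
    imaging of larval zebrafish. Converts multi-plane calcium movies into
    brain activity maps (BAMs) of per-region transient-count changes and
    replicate-level T-score BAMs, reduces them to 20-dimensional Pheno-Prints
    by principal component analysis, discovers phenotypic drug clusters by
    consensus clustering with bootstrap resampling, tests cluster association
    with WHO ATC therapeutic categories by the hypergeometric upper tail, and
    predicts therapeutic potential of unlabeled compounds with a random-forest
    classifier and Pearson-correlation ranking against signature-subgroup
    centroids. Includes a calibrated synthetic-data generator with planted
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    signal,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    tiff,
    EBImage
Config/testthat/edition: 3
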