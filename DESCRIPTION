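Package: fusedsdm
Title: Multilabel Species Distribution Models Fusing Aerial Imagery and Climate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multilabel, multi-taxonomic-rank species distribution
    modeling from 4-band aerial imagery and bioclimatic rasters. Curates
    citizen-science occurrence tables (spatial deduplication, range-confinement
    and minimum-count filters), builds community label sets by neighbor
    imputation, produces leakage-free buffered uniform and latitudinal-block
    train/test splits, and trains a fused residual convolutional image encoder
    plus climate multilayer perceptron with a sampling-aware binary
    cross-entropy that downweights absence evidence by estimated local survey
    completeness. Includes a per-species/per-observation accuracy metric suite
    with random and frequency baselines, strided sliding-window prediction
    maps, spatial and temporal community-change statistics, and a seeded
    virtual-ecosystem simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
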