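Package: msimg
Title: Density-Aware Multi-Channel Image Representation of LC-MS Runs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts LC-MS runs into multi-channel image tensors for
    phenotype classification. Each run is binned into a normalized
    scans-by-m/z matrix; signal-dense regions are located by density-map
    estimation and iterative non-maximum suppression; non-overlapping
    patch centers are chosen by a greedy density-aware maximum-coverage
    selection over the pooled training candidates; candidate locations
    are ranked by mean information entropy across the training set; and
    the top-ranked patches are stacked into a model-ready tensor per
    sample. Includes a synthetic LC-MS generator with planted peaks, a
    fixed-grid baseline candidate generator, redundancy diagnostics, and
    a lightweight linear-classifier separability check.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    mzR,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'daps.R'
    'density-nms.R'
    'io-text.R'
    'msimg-package.R'
    'patch-image.R'
    'pipeline.R'
    'spectra-io.R'
    'synthetic.R'
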