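Package: hsiband
Title: Wrapper Band Selection for Intraoperative Hyperspectral Tissue
    Classification
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying the most informative wavelength bands in
    visible/near-infrared hyperspectral images of exposed brain tissue.
    Implements the full processing chain: radiometric calibration against
    white/dark references, extreme-band removal, spectral smoothing and
    per-pixel min-max normalization; sampling-interval band decimation;
    balanced training-set reduction via per-class k-means clustering with
    spectral-angle prototype selection; wrapper band selection with genetic
    algorithm and binary particle swarm optimizers driven by penalized
    accuracy and balanced figure-of-merit fitness functions; ant-colony band
    ranking with top-k evaluation; leave-one-patient-out support vector
    machine evaluation with per-class metrics (sensitivity, specificity,
    Matthews correlation); and aggregation of per-fold band sets into
    coincidence levels and contiguous spectral ranges. A synthetic scene
    generator emulating hemoglobin absorption signatures of normal, tumor
    and hypervascularized tissue makes the whole pipeline exercisable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    e1071,
    png,
    data.table,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'bandselect.R'
    'classifier.R'
    'coincidence.R'
    'hsiband-package.R'
    'io.R'
    'metrics.R'
    'pipeline.R'
    'preprocess.R'
    'reduction.R'
    'synthetic.R'
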