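Package: maldiMilk
Title: Species-of-Origin Classification of Milk from MALDI-TOF Peak Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for authenticating the species of origin (bovine, goat,
    sheep) of milk samples from MALDI-TOF mass-spectrometry peak lists of the
    casein fraction. Reads per-run peak tables exported by acquisition
    software, applies quality-control filtering, extracts cross-run
    closest-mass consensus feature vectors, performs robust (median/IQR)
    scaling, and classifies vectors with a class-weighted feedforward neural
    network trained by mini-batch Adam. Includes 10-fold cross-validated
    evaluation with one-vs-rest ROC-AUC, confusion-matrix reporting,
    two-species mixture assessment, and a synthetic peak-list generator that
    emulates species-specific casein fingerprints for testing and
    benchmarking without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    readxl,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils-internal.R'
    'AllClasses.R'
    'AllGenerics.R'
    'methods-accessors.R'
    'preprocessing.R'
    'fnn.R'
    'evaluation.R'
    'peaklist-io.R'
    'synthetic-data.R'
    'pipeline.R'
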