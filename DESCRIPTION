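Package: netmark
Title: Biomarker Panel Discovery from Signed Protein-Network Model Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: In silico biomarker discovery over signed, directed
    protein-interaction networks. Builds disease-model ensembles by
    constrained signal propagation (stimulus / restrictions / response),
    samples solution ensembles of predicted protein activities in [-1, 1],
    derives differential-expression signatures, identifies minimal trigger
    sets by signed-path coverage, searches 1-3 protein classifiers scored
    by cross-validated balanced accuracy with exact binomial p-values, and
    prioritizes candidates through a specificity filter cascade with
    plasma/urine measurability annotation. Includes a synthetic-data
    generator with known ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
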