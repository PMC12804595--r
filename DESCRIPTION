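Package: cffat
Title: Multi-Task Cascade Forests for Cross-Species Acute Toxicity Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-task regression of continuous acute-toxicity endpoints
    (LD50/LDLo/TDLo across species and administration modes) with cascade
    forests and three knowledge-transfer mechanisms: aggregation of all
    endpoints into a source-domain model, feature enhancement by cascade
    layer transfer, and covariance-distance-guided greedy incorporation of
    neighbour endpoint samples. Includes molecular fingerprint
    featurization (Avalon, Morgan, AtomPair), a repeated cross-validation
    harness with R-squared and RMSE metrics, multi-view consensus
    ensembling, feature-importance association analysis, and a synthetic
    multi-task data generator for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
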