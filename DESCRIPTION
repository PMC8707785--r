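Package: cytosig
Title: Signature Cytokine Selection and Panel Design for Innate Immune
    Impurity Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multiplex cytokine immunoassays of PBMC
    cultures stimulated with innate immune response modulating impurities
    (IIRMIs), a drug product, and controls. Implements detection-limit
    censoring substitution, per-cytokine global standard-deviation
    normalization, control-based quality checks, exact tie-aware Wilcoxon
    rank tests, signature-cytokine and top-k selection against pooled
    negative controls, minimal set-cover construction of reduced biomarker
    panels, drug co-exposure modulation calls, and hierarchical clustering
    of treatment-response matrices. Includes a synthetic study generator
    with planted dose-response ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
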