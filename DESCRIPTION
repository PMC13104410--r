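Package: screenperm
Title: Docking Protocol Validation and Ex Vivo Permeation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Validation machinery for structure-based virtual screening
    protocols and analysis of ex vivo Franz diffusion cell permeation
    experiments. Computes in-place heavy-atom pose RMSD with optional
    symmetry correction, redocking success rates, enrichment factors and
    ROC-AUC against seeded decoy databases, applies validation thresholds
    to select docking/scoring combinations and call virtual-screening
    hits, and derives withdrawal-corrected cumulative permeation, steady
    state flux, apparent permeability, percentage transport and membrane
    integrity verdicts from Franz cell time series. Includes synthetic
    generators for docked pose ensembles with controlled RMSD,
    active/decoy score tables with controlled separation, and
    sink-condition permeation time courses, so every pipeline stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    bio3d,
    igraph,
    methods,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
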