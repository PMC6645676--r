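Package: ruptureNet
Title: Co-Expression Network and Cell-Population Analysis of Aneurysm
    Rupture Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for comparing ruptured and unruptured
    intracranial-aneurysm bulk transcriptomes across merged microarray
    cohorts. Provides merged-cohort preprocessing (quantile normalisation,
    log2 transform, global scaling), parametric empirical-Bayes batch
    correction, unsigned weighted gene co-expression network construction
    with topological-overlap module detection and eigengene-phenotype
    association, hypergeometric gene-set over-representation, marker-gene
    regression deconvolution of cell-population-specific expression with a
    three-part acceptance filter, Wang-method ontology semantic similarity
    with a rupture-specificity screen, and connectivity-map-style ranking
    of drug signatures by their ability to reverse a module-derived
    disease signature. A seeded synthetic-data generator with planted
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
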