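Package: ceRNAcross
Title: System-Level miRNA-Mediated ceRNA Crosstalk from Steady-State
    Titration Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic mass-action modelling of competing endogenous RNA
    (ceRNA) crosstalk on bipartite miRNA-RNA interaction networks. Solves the
    coupled titration fixed point for free RNA, miRNA and complex levels,
    computes the exact linear-response susceptibility matrix relating
    steady-state RNA levels to transcription-rate perturbations, and derives
    system-level crosstalk descriptors: mean and maximal susceptibility,
    incoming/outgoing selectivity, locality (correlation with a
    shared-regulator kernel), asymmetry, expression variability, and rank
    persistence under transcriptional heterogeneity. Includes lognormal
    transcription-rate ensembles, binding-heterogeneity scenarios over the
    four CLASH interaction classes, a CLASH-like synthetic interactome
    generator, and bipartite topology null models (uniform rewiring and
    degree-preserving edge swaps).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    igraph,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
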