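Package: spotniche
Title: Cytokine Microenvironment Analysis for Visium Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Maintainer", "Spotniche", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Density-based clustering of cytokine transcript-positive spots on
    the Visium hexagonal array, radius-of-action optimization via weighted
    Spearman correlation against cytokine responder-gene signatures, and the
    supporting stages: Visium-dialect input/output, spot and gene quality
    control, size-factor normalization, leukocyte/cytokine spot labeling,
    layer enrichment testing, responder-signature derivation from in-vitro
    stimulation tables, and negative-binomial GLM differential expression.
    Includes a synthetic Visium-like data generator with planted ground truth
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
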