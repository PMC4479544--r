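Package: connmtpc
Title: Multithreshold Permutation Inference for Structural Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Group analysis of structural brain connectomes built from
    streamline-count connectivity matrices. Provides threshold-indexed
    binarization (streamline-count and density-matched), the standard
    graph-theory metrics of network integration, segregation and centrality
    with analytic random-network normalization for smallworldness,
    multithreshold permutation correction (MTPC) of covariate-adjusted
    ANCOVA F statistics with a supra-critical cluster AUC decision rule,
    network-based statistics (NBS) on edges, functional-subnetwork
    derivation from volumetric statistical maps, and a seeded synthetic
    cohort generator for calibration and power studies.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
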