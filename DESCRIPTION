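Package: metalign
Title: Metabolic Network Alignment by Multilevel Graph Compression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Aligns two reaction-based metabolic networks at scale by first
    coarsening each network with minimum degree selection (MDS) compression
    into supernodes, aligning the compressed networks with a SubMAP-style
    support-matrix aligner, and then recursively refining supernode mappings
    back to the reaction level. Includes exact optimality oracles and bounds
    for the compression heuristic, a planner for choosing the compression
    level and deciding whether compression pays off, accuracy evaluation by
    score back-projection and Pearson correlation, degree-distribution
    analytics, and seeded generators for scale-free test networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
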