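Package: nucleomix
Title: Transient Crosslink Kinetics and Gene-Cluster Dynamics in the Nucleolus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Brownian-dynamics simulation of confined bead-spring chromosome
    chains with transient SMC-like crosslinking of nucleolar beads, together
    with the downstream analysis pipeline that links crosslink kinetics to
    gene-cluster dynamics: Hi-C-analogue pairwise-distance maps, weighted
    gene-interaction networks layered over time, multilayer-modularity
    community detection with a Louvain-style optimizer, bead- and
    community-level mixing statistics (interaction fraction, interaction
    number, waiting time, duration), cluster lifetime and persistence
    analysis, and a forward widefield-microscope simulator with the matching
    image-analysis pipeline (Otsu thresholding, signal normalization,
    nucleolar area, signal variability, and spot counting on maximum
    intensity projections).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    EBImage,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
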