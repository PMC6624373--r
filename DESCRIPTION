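Package: laminxl
Title: Quantitative SILAC Cross-Linking Analysis of the Lamin A Rod
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative SILAC cross-linking mass spectrometry
    (CLMS) of homo-oligomeric proteins, developed around the lamin A coiled-coil
    rod. Implements the 4-ion comparative quantification of light/heavy peptide
    pair precursor clusters into per-cross-link occurrence frequencies
    (inter-dimeric, inter-chain, intra-chain), ternary classification of
    cross-links, zero-length EDC chemistry rules, coordinate-model validation of
    cross-links by solvent-accessible-surface and side-chain contact distances,
    idealized coiled-coil construction, rod-length prediction with
    tandem-stagger compression, rank-based statistics for rod-length
    distributions, and ground-truth simulators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    Rcpp,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    jsonlite
Config/testthat/edition: 3
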