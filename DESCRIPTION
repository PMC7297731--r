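Package: wphom
Title: Weighted Persistent Homology Descriptors for Molecular Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topological descriptors of coarse-grained molecular point
    configurations in periodic boxes. Implements localized persistent
    homology (per-molecule Vietoris-Rips barcodes within a cutoff sphere),
    interactive persistent homology (bipartite osmolyte-water dissimilarity
    matrices with infinite same-type entries), persistent Betti number
    curves, persistent entropy, Boltzmann persistent entropy, and the
    persistent radial distribution function, together with seeded synthetic
    configuration generators, multi-frame XYZ/GRO readers, coarse-graining
    rules, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
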