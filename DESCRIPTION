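Package: icenuc
Title: Crystal Nucleation in Coarse-Grained Water with Classical and
    Neural-Network Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Molecular simulation and analysis toolkit for homogeneous ice
    nucleation in the mW (Stillinger-Weber form) coarse-grained water model.
    Provides the mW potential with forces and virial, NVE/NVT/NPT molecular
    dynamics, a descriptor-based neural-network potential with trainable
    atomic fingerprints and its training loop, Q12 bond-orientational
    crystallinity analysis with largest-cluster decomposition, mean
    first-passage-time extraction of nucleation rates and critical sizes,
    and umbrella sampling of nucleation barriers with a classical-nucleation-
    theory-shaped bias driven by hybrid Monte Carlo. Includes synthetic-data
    generators (diamond lattices, equilibrated liquids, birth-death nucleation
    walks, one-dimensional landscapes) used to validate every estimator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
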