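Package: phylosense
Title: Phylogenetic Comparative Analysis of Visual-Olfactory Sensory Investment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the allocation of sensory investment between
    vision and olfaction across Drosophila species and testing its phylogenetic
    structure. Builds derived traits from raw head and antennal morphometrics
    (half-ellipsoid eye surface area, ovoid funiculus surface area, the
    eye-to-funiculus ratio, sensillum densities, neuropil volume ratios, disc
    ratios and two-choice attraction indices), checks isometric size scaling,
    and provides from-scratch phylogenetic comparative statistics: the Brownian
    variance-covariance matrix from a tree, Blomberg's K with a permutation
    test, maximum-likelihood estimation of Pagel's lambda, and phylogenetic
    generalized least squares with Brownian or ML-lambda error structure.
    Seeded generators for pure-birth trees, lambda-transformed Brownian traits,
    latent-threshold binary traits and full morphometric specimen tables make
    every pipeline stage testable by simulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    withr,
    optparse
Config/testthat/edition: 3
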