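Package: morphoplace
Title: Maximum-Likelihood Placement of Sequence-Less Taxa on Ultrametric
    Trees Using Continuous Morphological Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Places a taxon for which no molecular data exist (for example
    a historical type specimen) into a time-calibrated molecular phylogeny
    using continuous morphological measurements under a Brownian-motion
    model of trait evolution. Multiple traits are combined through a
    phylogenetic principal component analysis; every branch of the tree is
    then scored by profile maximum likelihood for attachment of the query,
    exploiting a rank-one Cholesky update of the phylogenetic covariance
    matrix. Includes a prune-and-replace randomization test that compares
    maximum-likelihood against random placement with branch-score and
    quadratic path tree distances, a parametric-bootstrap likelihood-ratio
    test of clade-constrained placements, birth-death simulators for trees
    and clade-shifted trait data, and one-way ANOVA utilities for spore
    and basidia morphometrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    phytools,
    phangorn,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
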