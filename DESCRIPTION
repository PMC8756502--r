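Package: admixkit
Title: Simulation and Inference of Continental and Subcontinental Genetic
    Admixture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for studying admixed human populations on
    simulated data: Balding-Nichols founder-panel simulation with
    recombination along a genetic map, supervised maximum-likelihood
    estimation of genome-wide ancestry fractions, Shannon admixture entropy,
    KING-robust kinship filtering, windowed local-ancestry inference with
    certainty-threshold masking, haplotype-painting profiles converted to
    subcontinental ancestry proportions by non-negative least squares with a
    simulation-grid validation harness, X-versus-autosome sex-biased
    admixture statistics, Hudson F_ST with neighbor-joining trees and
    outgroup f3, and single-pulse admixture dating from ancestry tract
    lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    pracma,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
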