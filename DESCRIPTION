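Package: coalcnn
Title: Coalescent Simulation and Convolutional Model Choice for Island
    Colonization Scenarios
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based phylogeographic model selection for archipelago
    colonization histories. Simulates unlinked biallelic SNP matrices under
    alternative colonization scenarios of the Canary Islands (central island
    hub; east-to-west surfing syngameon, with or without back-colonization of
    the African mainland) using a structured coalescent with founder-effect
    bottlenecks, exponential population recovery and time-windowed migration.
    Encodes the matrices as major/minor-allele images, trains a
    one-dimensional convolutional network to discriminate the scenarios,
    calibrates it by temperature scaling, and feeds the class-probability
    summaries into an approximate Bayesian computation rejection step to
    obtain model posterior probabilities and parameter posteriors. Also
    provides the SNP post-filters (missing-data and proximity thinning) and
    per-population diversity statistics (observed and expected
    heterozygosity, rarefied allelic richness, Shannon diversity, Watterson's
    theta, Tajima's D) used alongside such analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
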