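Package: demic
Title: Spatially Explicit Demic Expansion Simulation and Serial-Founder
    Population Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher simulation of demic range
    expansions on a deme lattice with scenario-specific habitability
    (routes around or through a barrier), and the statistical toolkit used
    to tell a serial-founder expansion from isolation by distance:
    rarefied haplotype richness and haplotype heterozygosity, linkage
    disequilibrium decay, runs of homozygosity, Hudson FST with f3/f4
    statistics and block-jackknife errors, Mantel and partial Mantel
    permutation tests, PCA with Procrustes alignment to geography,
    local-ancestry tract masking with exponential tract-length admixture
    dating, origin-anchored FST route tracing and hexagonal FST gradient
    surfaces.  Includes synthetic-data generators (serial-founder,
    stepping-stone, island-model and admixed panels plus cognate matrices
    evolved on the founding tree) so the whole pipeline is testable at
    desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
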