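Package: ginkgopop
Title: Coalescent Simulation and Population-Genomic Inference for a
    Four-Lineage Split-and-Admixture Demography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable population-genomics pipeline around the
    demographic history of ginkgo (Ginkgo biloba): a structured-coalescent
    simulator for split-plus-admixture demographies (genealogies, expected
    site frequency spectra, genotype matrices with optional injected
    selective sweeps), diversity and differentiation statistics (pi,
    Watterson's theta, expected heterozygosity, Hudson's FST, joint SFS),
    identity-by-state distances with a dispersal classification, structure
    inference (PCA on the variance-standardized relationship matrix,
    neighbor-joining trees, ADMIXTURE-style block-relaxation ancestry
    estimation with cross-validation), SFS composite-likelihood demographic
    fitting with AIC/Akaike-weight model comparison and parametric
    bootstrap, and a two-pronged selection scan (Z-scored windowed
    heterozygosity and FST plus a SweepFinder-style composite likelihood
    ratio test).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
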