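Package: dragoncolour
Title: Heritability of Dorsal Colour Pattern from Standardised Swatch Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies dorsal colouration of lizards from standardised
    rectangular swatch images (overall brightness, elongation of the
    longitudinal pattern, and light-dark contrast) and estimates the
    narrow-sense heritability of each metric with a Bayesian animal model
    fitted by Gibbs sampling over a pedigree-derived additive relationship
    matrix. Includes a synthetic-data generator that emulates a split-clutch
    thermal-treatment breeding design (pedigree, covariates, latent trait
    values and rendered swatch images with known ground truth), a direct
    REML oracle for cross-checking the sampler, posterior summaries
    (kernel-density modes, highest posterior density intervals, pMCMC) and
    convergence diagnostics, plus drivers that run the full
    swatches-to-heritability analysis reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    coda,
    jsonlite,
    methods,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
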