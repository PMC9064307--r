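Package: morphoevo
Title: Morphological Disparity and Evolutionary Rates from Discrete Character Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for macroevolutionary analysis of discrete morphological
    character matrices on dated phylogenies: maximum observable rescaled
    distances (MORD), principal coordinates morphospace with time-binned
    occupation and convex-hull areas, bootstrapped and rarefied sum-of-variances
    disparity through time, a-posteriori time-scaling of cladograms from
    stratigraphic ranges (equal, minimum branch length, and Bayesian
    successive-outgroup node dating), per-branch and per-bin maximum-likelihood
    rates of discrete character evolution with likelihood-ratio tests, PAM
    morphospace clustering and character-axis Cramer coefficient profiles, and
    a birth-death plus Mk-model synthetic data generator for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    cluster,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
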