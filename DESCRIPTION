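Package: aneumorph
Title: Synthetic-Phantom Pipeline for Aneurysm Morphometry and First-Coil Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully synthetic re-implementation of a deep-learning
    surgical-planning pipeline for unruptured intracranial aneurysm (UIA) coil
    embolization. Generates subtracted-CTA-like vascular phantoms (parent vessel
    plus spherical-cap aneurysm) with analytic ground truth, segments them with a
    residual 3D U-Net trained with a combined cross-entropy and
    exponential-logarithmic Dice loss, measures the five standard aneurysm
    morphometric features (size, height, neck diameter, dome diameter, volume)
    from binary masks, and recommends the diameter of the first framing coil with
    a neural factorization machine, evaluated by Dice-family scores, intraclass
    correlation, and absolute/general match ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
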