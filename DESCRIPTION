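Package: rdresponse
Title: Reaction-Diffusion Modeling of Radiotherapy Response in PET Images
    with a Learned Dose-Response Operator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts post-radiotherapy FDG-PET standardized uptake value
    (SUV) images from pre-treatment images and planned spatial dose
    distributions. The dynamics follow a reaction-diffusion partial
    differential equation U_t = alpha * Laplacian(U) + beta * U + F(D * U)
    whose dose-response operator F is learned by a small encoder-decoder
    convolutional network embedded in an unrolled forward-Euler solver with
    two trainable physical coefficients (diffusion alpha, proliferation
    beta). Includes a seeded synthetic phantom generator, NIfTI input and
    output, slice eligibility filtering, and the full evaluation protocol:
    Otsu high-uptake segmentation, Dice overlap, SUV statistics, and
    multi-criteria 2D gamma-index analysis with passing rates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
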