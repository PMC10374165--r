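Package: structpca
Title: Structured PCA via Bayes-Optimal Approximate Message Passing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rank-one spiked matrix estimation when the noise is a
    rotationally invariant random matrix from a polynomial trace ensemble
    (quartic, sextic) rather than a Wigner matrix.  Generates spiked datasets
    whose noise spectrum follows the one-cut equilibrium measure of the
    potential, computes spectral quantities (moments, free cumulants,
    Stieltjes transform, BBP outlier and overlap theory), constructs the
    optimal polynomial preprocessing of the data matrix, and runs the
    Bayes-optimal approximate message passing algorithm (BAMP) together with
    its multistage state evolution, plus baseline AMP variants and the
    rescaled spectral (PCA) estimator, to reproduce mean-square-error versus
    signal-to-noise phase diagrams on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
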