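Package: tiapbms
Title: Population-Based Model Selection for Time-Integrated Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for internal dosimetry curve fitting on sparse
    radiopharmaceutical time-activity data. Candidate sum-of-exponential
    kinetic functions are fitted population-wise with a non-linear
    mixed-effects model (log-normal inter-individual variability,
    multiplicative residual error, Laplace-approximated marginal
    likelihood); candidates are gated on the coefficients of variation of
    their fixed effects and ranked by small-sample-corrected Akaike
    weights; per-patient time-integrated activities are reported per
    function and as the Akaike-weight model average. Individual-fit and
    shared-parameter population baselines, frequency-based uncertainty
    propagation for their TIAs, leave-one-out selection stability and a
    synthetic study-design cohort generator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
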