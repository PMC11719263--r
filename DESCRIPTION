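Package: likertnet
Title: Regularised Partial-Correlation Networks for Ordinal Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimation and validation of sparse Gaussian graphical models
    over 5-point Likert survey items, as used in cross-country lifestyle and
    health-outcome network studies. Provides topological-overlap screening of
    redundant items, EBIC-tuned graphical lasso estimation of partial
    correlation networks (solver included, written in C++), expected-influence
    and one-step bridge expected-influence centralities, nonparametric and
    case-dropping bootstrap machinery with the correlation-stability
    coefficient, Holm-adjusted Wilcoxon centrality difference tests, a
    per-country analysis pipeline, and a latent-Gaussian ordinal data
    generator with known sparse two-community truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
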