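Package: attritioniv
Title: Instrumental-Variables Estimation of Attrition in Online Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures emotions and network centrality from user-generated
    content, constructs followee-based instruments, builds interval-censored
    dropout outcomes, and estimates the causal effect of emotions and coreness
    centrality on dropout with two-stage least squares (linear-probability
    models) and a control-function instrumental-variables extension of Aalen's
    additive hazards model.  Includes a synthetic community generator that
    reproduces the statistical structure the estimators assume (directed
    homophilous follow graph, peer-correlated emotions, unobserved confounding,
    hazard-driven dropout, Poisson posting streams, topic-conditioned hashtags)
    so the full pipeline can be exercised and validated without access to any
    platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
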