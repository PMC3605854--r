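Package: coalabc
Title: Coalescent Simulation and Approximate Bayesian Computation for
    Island Colonization Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage inference of population histories from mitochondrial
    sequence and microsatellite data. Implements mismatch-distribution
    demographic-expansion analysis with sudden-expansion model fitting,
    parametric-bootstrap goodness-of-fit and tau-to-time dating; and a
    structured-coalescent simulator (population splits, founder bottlenecks,
    HKY+Gamma+invariant-sites sequence evolution, generalized stepwise
    microsatellite mutation) driving approximate Bayesian computation over
    order-constrained colonization scenarios: rejection, logistic-regression
    scenario choice, local-linear parameter adjustment, and validation by
    PCA pre-evaluation, model checking, confidence in scenario choice, and
    bias/precision on pseudo-observed datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    ape,
    nnet,
    mgcv,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
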