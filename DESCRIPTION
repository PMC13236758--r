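Package: soprec
Title: Simulating Object Recognition with the SOP Opponent-Process Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative simulator of Wagner's Standard Operating Procedures
    (SOP) associative model applied to object-recognition procedures
    (spontaneous object recognition, relative recency, object-in-place and
    multi-sample variants). Integrates the coupled node/link differential
    equations with fixed-step fourth-order Runge-Kutta, builds conceptual and
    empirical stimulus schedules with full counterbalancing enumeration,
    converts trajectories to peak-A1 exploration readouts, fits a weighted
    least-squares activation-to-seconds observation model with an exact
    study-level bootstrap, and evaluates robustness with parameter space
    partitioning, Sobol' variance decomposition, and a local two-level
    factorial analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
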