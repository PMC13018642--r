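Package: iobntsim
Title: Closed-Loop IoBNT Drug-Delivery Simulator with Compartmental
    Pharmacokinetics, Safety-Constrained Control and Chaotic Privacy
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulator of an AI-guided Internet-of-Bio-NanoThings
    therapeutic loop for doxorubicin delivery. Provides stimulus-triggered
    liposomal release kinetics, a five-compartment forward pharmacokinetic
    model of transport from systemic plasma to tumor intracellular space, a
    reverse-path molecular-communication model with a bioluminescent reporter
    chain, a confidence-driven supervisory dose controller with hard safety
    constraints, a quadratic-map chaotic privacy and authentication layer,
    Monte-Carlo uncertainty propagation with 90 percent prediction intervals,
    one-at-a-time sensitivity sweeps, misclassification-robustness
    experiments, and deployment throughput/storage arithmetic for the
    ingestible imaging device. Includes a reproducible experiment runner and
    a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
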