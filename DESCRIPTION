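Package: vctsim
Title: Virtual Clinical Trial Simulation of Platinum-Resistance Evolution
    in Ovarian Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multitype branching-process model of the evolution of
    platinum resistance in high-grade serous ovarian cancer under
    first-line therapy (neoadjuvant chemotherapy, interval debulking
    surgery, adjuvant chemotherapy), with hybrid
    stochastic-deterministic and exact Gillespie simulation engines.
    Provides virtual patient simulation, randomized and
    biomarker-stratified virtual clinical trial simulators with
    Kaplan-Meier and log-rank readouts, targeted-drug efficacy
    modelling for agents directed at pre-, on- and post-target
    resistance mechanisms, and grid-search calibration of the
    resistance parameters against platinum-free-interval cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
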