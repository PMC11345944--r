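Package: gastroPK
Title: Gastric-Motility Deduction from Oral-Capsule Pharmacokinetics via
    Coupled Dissolution and Absorption-Transit Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Physiologically based biopharmaceutics modelling (PBBM) toolkit
    that links in vitro capsule dissolution under programmable gastric
    stress/flow conditions to in vivo plasma pharmacokinetics. Implements a
    digital twin of a closed-loop flow-through dissolution apparatus with
    Weibull capsule release and modified Noyes-Whitney particle dissolution,
    a six-compartment gastrointestinal absorption-transit model with variable
    first-order gastric emptying and a housekeeper-wave event, a
    two-compartment population pharmacokinetic disposition model with
    log-normal between-subject variability and two-stage individual fitting,
    rule-based classification of plasma profiles into six gastric-motility
    groups, and prevalence-weighted virtual-population trial simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
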