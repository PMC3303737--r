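Package: ribocell
Title: Deterministic and Stochastic Simulation of an RNA-Based Minimal Cell
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the Ribocell, a hypothetical minimal cell in which a
    self-replicating RNA genome (a polymerase ribozyme and a lipase ribozyme,
    each with its complementary template strand) is coupled to a
    self-reproducing fatty-acid vesicle. Provides the full reaction network
    (reversible strand hybridisation, template-directed transcription,
    catalysed lipid synthesis), membrane transport and lipid exchange
    channels, and osmotically coupled vesicle volume dynamics. Two engines
    are included: a stiff ODE integrator for the average vesicle with event
    detection for division and osmotic burst, and a Gillespie direct-method
    stochastic engine (with an optional hybrid leaping accelerator) for
    populations of individual vesicles with binomial partitioning of
    molecules at division. Utilities cover genome census, protocell
    classification, generation statistics and stationary-regime parameter
    scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
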