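Package: ivdds
Title: Transport Kinetics of Intravascular Triggered Drug Delivery Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational model of intravascular triggered drug delivery
    systems (IV-DDS) such as temperature-sensitive liposomes: a quasi-steady
    microvascular concentration-gradient model coupled to a systemic/tumor
    compartmental pharmacokinetic model, together with parameter estimation
    from intravital fluorescence and blood-sampling data, release-kinetics
    characterization, key-index (release/permeability) plateau analysis,
    parametric mapping, Monte Carlo uncertainty propagation, and Sobol global
    sensitivity analysis. Includes seeded synthetic-data generators for every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
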