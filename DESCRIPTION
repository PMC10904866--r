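Package: drscreensim
Title: Agent-Based Simulation of Adherence to Diabetic Retinopathy Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete-time agent-based simulation of population adherence to
    diabetic retinopathy screening programs. Each simulated diabetic decides
    whether to attend each screening call through one of three interchangeable
    decision engines: a logistic regression on screening history, a Mamdani
    fuzzy-inference system built from three Health-Belief-Model components
    (access barriers, knowledge of the disease, quality of the screening
    strategy), or a weighted combination of the two. Includes a synthetic
    population generator structured like a regional screening registry
    (eight subregions, demographic clusters, per-agent screening histories),
    stepwise logistic calibration from call records, intervention scenarios,
    replicate runs, and confidence-interval reporting of regional adherence
    rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
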