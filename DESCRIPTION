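Package: n400frames
Title: Frame-Based Hybrid Model of the N400 Component
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational model of the N400 event-related potential as a
    function of two components computed over stochastic frames: a
    predictability component (entropy reduction over non-disconfirmed
    category features) and a plausibility component (prototype-theoretic
    typicality via min-rule similarity weighted by attribute
    diagnosticity). Category concepts are represented as sorted
    attribute-value structures carrying probability distributions; default
    inferences follow a statistical-consequence threshold rule. Ships
    worked scenario fixtures, a seeded synthetic scenario generator, a JSON
    scenario format with validation, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
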