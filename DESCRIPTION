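Package: flapmode
Title: Modal Effective Mass Analysis of Running Bipeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles lumped mass-spring models of bipedal animals (a
    central body carrying wings, legs, tail and neck/head, grounded through
    foot springs), solves the undamped free-vibration eigenproblem, and
    computes modal participation factors and effective masses to identify
    which vibration modes footfall forcing can excite. Natural frequencies
    are mapped to resonant running speeds through stride length and bounded
    by a Froude-number speed limit; a damped forced-response simulator
    (frequency-response functions and implicit time integration under
    periodic footfall base excitation) quantifies the wing oscillation each
    running speed produces; and interval arithmetic propagates uncertain
    masses, stiffnesses and step lengths to guaranteed bounds on frequencies
    and resonance speeds. Ships the seven-degree-of-freedom Caudipteryx
    model whose flapping-mode resonance motivates the pipeline, plus
    generators for mass-scaled and randomized model families.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
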