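Package: whiskloop
Title: Discrete-Event Statechart Simulation of the Rat Whisking Brainstem Loop
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An executable-statechart model of the brainstem sensorimotor loop
    that drives rhythmic whisking in rats. Three central pattern generators
    excite pools of facial motoneurons, which contract intrinsic and extrinsic
    mystacial-pad muscles and sweep an array of 29 rigid whiskers; whisker-object
    contact is transduced by four classes of trigeminal afferents (whisking,
    contact, pressure, detach) whose feedback can excite retractor motoneurons or
    inhibit protractor drive, reproducing touch-induced pumps (TIPs). Includes a
    deterministic discrete-event scheduler, network construction for the
    alternative whisking- and TIP-generating circuit configurations, parameter
    calibration against published kinematic benchmarks, and an analysis layer
    that segments whisk cycles, detects and characterises pumps, and generates
    synthetic tracked-whisker traces for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
RoxygenNote: 7.3.3
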