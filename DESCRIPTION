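Package: mockloop
Title: Lumped-Parameter Simulation and Validation Statistics for a
    CMR-Compatible Mock Circulatory Loop
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the haemodynamics of an aortic-arch mock circulatory
    loop as a lumped-parameter network: four downstream branches, each a
    non-linear tap resistance in series with a linear tube resistance and a
    Windkessel compliance, fed through a zero-dimensional junction and
    drained through a common terminal section into a constant-pressure
    atrial reservoir. Generates pulsatile pump-like inlet waveforms,
    emulates phase-contrast MR sampling of the inlet curve, integrates the
    network ODEs with fixed-step explicit Euler to a periodic regime, and
    computes the validation statistics used to compare measured and
    simulated haemodynamics: flow splits, percentage errors, R-squared, and
    Bland-Altman limits of agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
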