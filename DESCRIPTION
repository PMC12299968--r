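Package: blmchannel
Title: Single-Channel Current Analysis for Black Lipid Membrane Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-channel ionic currents recorded from
    planar (black) lipid membranes, motivated by studies of amyloid-beta
    oligomer pore formation. Simulates seeded, ground-truth-labelled current
    traces with spike, bump, step and erratic event classes; idealizes noisy
    traces into discrete events by hysteresis thresholding over a robust
    baseline; classifies events by shape features; summarises per-class
    conductance and lifetime statistics; estimates cylindrical pore diameters
    from conductance via a Hille-type model calibrated against the gramicidin
    channel; and analyses particle z-height distributions in atomic force
    microscopy topographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
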