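Package: photwin
Title: Digital Twin of an Open RGB-LED Photometer for Ellman Cholinesterase Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an open-hardware photometric platform built from a
    colour-programmable RGB LED source and a light-to-frequency sensor, and
    implements the full Ellman cholinesterase analysis path on top of it.
    The optics module maps a requested wavelength to PWM duties and models
    the LED emission spectrum; the chemistry module integrates Ellman
    reaction kinetics with Michaelis-Menten substrate dependence and
    pseudo-first-order carbamate inactivation of acetylcholinesterase; the
    sensor module converts transmitted light to pulse frequencies with
    Poisson counting noise; the analysis module provides endpoint and
    kinetic evaluation, Michaelis-Menten fitting, inhibitor calibration
    with limit-of-detection estimation, and preincubation-time
    optimization. Instrument streams are read and written in a
    comma-separated dialect compatible with spreadsheet data-streaming
    add-ins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
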