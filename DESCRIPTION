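Package: relaxbp
Title: Relaxation-Oscillator Modelling of Blood Pressure, Heart Rate, and
    Vaso-Vagal Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates arterial blood pressure as the output of a discrete-time
    second-order relaxation oscillator with baroreflex-like threshold and
    saturation feedback, a Desired-BP reference drive, and a vestibular
    (otolith) input coupled into the feedback loop.  Provides stimulus
    generators (Desired-BP profiles, sinusoidal galvanic vestibular
    stimulation, tilt, and stochastic threshold processes), analysis operators
    for pressure traces (systole/diastole detection, heart rate, pulse
    pressure, phase-plane trajectories, baroreflex sensitivity by the
    sequence method, band power, and harmonic decomposition), and scenario
    presets that reproduce the model's characteristic behaviours: normal
    oscillation, the vestibulo-sympathetic reflex, and vaso-vagal responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
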