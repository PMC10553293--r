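Package: diffenc
Title: Motion-Compensated Diffusion Encoding Gradient Waveform Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis of symmetric, concomitant-field-balanced
    gradient waveforms for spin-echo diffusion MRI. Represents encoding
    schemes as trapezoidal gradient pulses around a refocusing pulse,
    computes gradient moments (M0, M1, M2) and b-values of the effective
    waveform in closed form, constructs monopolar, velocity-compensated and
    acceleration-compensated encodings, and tunes the residual velocity- and
    acceleration-weighting continuously through a single timing-shift
    parameter. Includes closed-form rectangular-pulse oracles, a small
    ballistic-flow (IVIM-type) liver signal model with two-point ADC
    estimation, waveform file I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
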