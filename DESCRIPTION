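Package: cathwave
Title: Fidelity of Fluid-Filled Catheter Pressure Measurements in Pulsatile Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for quantifying the measurement bias that a
    fluid-filled catheter introduces into invasive blood-pressure recordings.
    Simulates pulsatile pressure in a compliant vessel with and without an
    inserted coaxial catheter using a reduced-order one-dimensional pulse-wave
    model with Windkessel afterload, distorts the "measured" signal through a
    second-order catheter-manometer model, and quantifies the resulting biases
    in peak pressure, pulse pressure, waveform spectrum and foot-to-foot pulse
    wave velocity against an ideal (pressure-wire-like) measurement. Includes
    a synthetic arterial-waveform generator, annular-obstruction resistance
    formulas, zero-padded amplitude spectra and a curvature-sum air-bubble
    quality check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
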