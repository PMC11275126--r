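Package: neuroemi
Title: Equivalent-Circuit Modeling of Electromagnetic Interference in
    Multichannel Neural Recording
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phasor-domain equivalent-circuit models for extracellular
    neural recording: dipole sources in a resistive volume conductor, the
    three-electrode (signal/reference/ground) signal path to a differential
    amplifier, capacitive power-line coupling through the body and recording
    hardware, and the decomposition of the resulting interference into
    common-mode and differential-mode components at the amplifier input.
    Includes an executable checker for six electrode-design guidelines, a
    seeded synthetic-recording generator (biphasic spikes, band-limited
    local field potential, model-scaled 50 Hz interference), Welch spectral
    analysis, and a staged interference-rejection experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    rlang,
    signal,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
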