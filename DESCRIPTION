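Package: flowSIM
Title: Digital Twin of an Optofluidic Light-Sheet Structured-Illumination
    Imaging Flow Cytometer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses an integrated optofluidic 3D imaging
    flow cytometer in which two on-chip light sheets interfere to form a
    sinusoidal structured-illumination pattern, a thermal phase shifter
    steps the pattern phase (phase proportional to dissipated electrical
    power, i.e. to drive voltage squared), and cells flowing at constant
    speed are sectioned plane by plane. Provides a closed-form optical
    forward model, emitter-based phantom generators (uniform dye, bead
    fields, membrane-labelled cells), a camera acquisition simulator with
    Poisson and read noise, fringe-calibration analysis (sub-pixel peak
    tracking, period and voltage-to-phase estimation), three-phase
    single-orientation structured-illumination reconstruction (band
    separation, carrier estimation by Fourier cross-correlation, Wiener
    recombination), and flow-scan volume assembly with throughput
    accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
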