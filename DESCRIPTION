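Package: flexmea
Title: Reliability Analysis of Flexible Graphene Microelectrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for assessing the chronic reliability of thin-film
    (graphene-on-polymer) microelectrode arrays. Implements an equivalent
    circuit model of the graphene/electrolyte interface (series resistance,
    constant phase element, quantum capacitance, charge transfer resistance
    and bounded Warburg diffusion) with complex nonlinear least-squares
    fitting of impedance spectra; accelerated-aging lifetime equivalence
    based on the 2^(dT/10) rule; longitudinal tracking of per-channel 1 kHz
    impedance with yield and failure-day detection; quantification of saline
    permeation from grayscale microscope images (thresholding, percent area,
    maximum permeation distance); quality metrics for chronic
    electrocorticography recordings (RMS noise, stimulus-locked averaging,
    onset latency, band-power spectrograms); and seeded synthetic-data
    generators that emulate every input so the full pipeline is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    EBImage,
    signal,
    jsonlite,
    yaml,
    png,
    tiff,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
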