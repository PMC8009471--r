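Package: nirheat
Title: Photothermal Heating of Nanoparticle-Coated Substrates: Model,
    Calibration and Image Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the temperature increment produced by near-infrared (NIR)
    laser irradiation of a nanoparticle-coated glass substrate as a
    one-dimensional axisymmetric heat-conduction problem with surface exchange,
    solved by the method of lines. Calibrates the effective particle absorption
    fraction by least squares against step-end intracellular temperature
    observations, converts temperature-sensitive dye fluorescence traces to
    temperature increments, quantifies particle occupancy fractions and
    mitochondrial roundness from images, and generates synthetic data with
    known ground truth to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
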