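Package: cardiotox
Title: Quantitative Imaging and Kinetics Readouts for Cardiomyocyte Toxicity Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational readouts for anthracycline cardiotoxicity screens on
    stem-cell-derived cardiomyocytes: FFT-bandpass quantification of sarcomere
    striation and myofibril organization from alpha-actinin micrographs,
    coverage-fraction viability from Calcein/GFP fields, calcium- and
    force-transient kinetics (frequency, time-to-peak, time-to-decay,
    velocities, diastolic load), gamma-H2AX focus scoring per nucleus, and
    saturating-exponential drug uptake and washout model fits. Includes
    seeded synthetic-data generators with exact ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
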