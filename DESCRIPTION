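Package: flickerspec
Title: High-Throughput Flicker Spectroscopy of Biomolecular Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the interfacial tension and bending rigidity of
    biomolecular condensates (e.g. stress granules) from time-lapse fluorescence
    microscopy by flicker spectroscopy. Detects granules with a
    difference-of-Gaussians detector, tracks them across frames, extracts
    sub-pixel radial boundaries by maximum-gradient ray casting, decomposes
    boundary fluctuations into Fourier modes with a base-shape (static mode)
    correction, and fits the time-averaged spectrum to the projected Helfrich
    prediction to estimate tension and rigidity per granule, with
    population-level log-normal summaries. A synthetic-data subsystem generates
    equipartition-sampled fluctuating droplets, rotating rigid bodies, and
    microscope-like renderings so every stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
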