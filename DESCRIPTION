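Package: forelule
Title: Forel-Ule Colour Index Toolkit for Water Colour and Quality
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives the Forel-Ule colour index (FUI, 21 classes from
    indigo-blue to cola brown) of natural waters from hyperspectral
    remote-sensing reflectance via CIE 1931 tristimulus colorimetry and
    hue angles, both as discrete classes and as continuous one-decimal
    indices. Provides the validation statistics used in water-colour
    field studies (mean absolute / mean percent difference, Spearman rank
    association, linear bias correction against handheld scale readings),
    CDOM spectral-slope fitting, multivariate regressions linking FUI to
    colour-producing agents, fixed-platform time-series reduction, and
    GeoJSON station-map export. A simple bio-optical forward model
    generates synthetic campaigns so the entire pipeline can be exercised
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
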