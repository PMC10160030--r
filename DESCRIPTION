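Package: rootMSI
Title: DESI Mass Spectrometry Imaging Analysis Along the Root Developmental Axis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for desorption electrospray ionization mass spectrometry
    imaging (DESI-MSI) of plant root sections along the developmental axis:
    an imzML 1.1 reader/writer with an in-memory pixel-raster data model,
    theoretical adduct m/z calculation from molecular formulas, single-ion
    image extraction with ppm mass-tolerance windows and per-pixel total ion
    current (TIC) normalization, per-pixel ratio images, band-averaged
    longitudinal intensity profiles with per-position Student t-tests,
    lateral-resolution estimation by the 80-20 percent edge rule with
    point-slope line fitting, background-subtracted zone-averaged spectra,
    meristem-versus-differentiation expression enrichment scores, and a
    synthetic root-section simulator that provides ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
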