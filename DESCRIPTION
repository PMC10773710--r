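Package: canopyspad
Title: Vertical SPAD Distribution Modelling and Multispectral Inversion for Maize Canopies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the vertical distribution of relative
    chlorophyll content (SPAD values) in maize canopies and linking it to
    UAV-style 5-band multispectral reflectance. Fits the Lorentz peak
    distribution function to vertical SPAD profiles per nitrogen treatment
    and growth stage, computes 17 chlorophyll-related vegetation indices
    from plot reflectance, screens leaf positions for sensitivity to a
    chosen index, and builds simple linear inversion models of SPAD from
    vegetation indices. Includes a synthetic campaign generator with known
    ground truth (bell-shaped profiles plus co-varying reflectance) and a
    fixture-raster toolkit for region-of-interest mean reflectance
    extraction, so the full pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
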