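Package: nirschange
Title: Block-Design Change-Detection Analysis for Infant and Adult fNIRS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for functional near-infrared spectroscopy
    (fNIRS) change-detection (oddball) block designs: probe-lattice channel
    geometry, jittered block-design stimulus scheduling, conversion of
    dual-wavelength optical density to hemoglobin concentration changes via
    the modified Beer-Lambert law, motion-artifact detection on band-passed
    total hemoglobin with zero-weight exclusion, artifact-weighted general
    linear models with canonical-HRF condition regressors and sine/cosine
    detrending, Monte-Carlo max-statistic (Westfall-Young style) channel
    significance, finite-impulse-response reconstruction of the hemodynamic
    response, laterality indices from region-of-interest peak responses, and
    a ground-truth-known synthetic multichannel recording generator for
    validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
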