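Package: seedmd
Title: Monte Carlo Quantification of Internal Microdamage in Seed
    Cross-Section Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies internal microdamage (cracks) in stacks of
    tomographic cross-section images of seeds and similar loose biological
    objects.  Provides a synthetic phantom generator with exact pixel-level
    ground truth, polarity normalisation and threshold-based crack
    segmentation, a Monte Carlo point-classification estimator of the
    microdamage coefficient with normal-approximation confidence
    intervals, specimen-level aggregation over 20-section stacks, and a
    virtual loading study relating the damage level to external static and
    dynamic load parameters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
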