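Package: facesym
Title: Automated Facial Symmetry Scoring for Peripheral Facial Palsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies dynamic facial asymmetry in patients with peripheral
    facial palsy from standardized frontal photographs. Expression images are
    registered to a neutral reference via a landmark-based similarity
    transform, masked to the facial region, and differenced; the smoothed,
    amplified difference image yields both a rainbow heatmap of facial
    movement and a variance-weighted left/right symmetry score in [0, 1].
    Per-patient score series over therapy are summarized with a rolling
    median, a Theil-Sen robust slope and a conservative trend label, and
    can be correlated with ordinal clinical grades via Spearman's rank
    correlation. A procedural face-image generator with a matching
    478-point landmark template makes the full pipeline testable without
    patient data or an external landmark model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    jpeg,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
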