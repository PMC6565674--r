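Package: fcscreen
Title: Brain-Wide Functional Connectivity Fingerprinting for Neuromodulator
    Polytherapy Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for selecting complementary drug combinations
    from brain-wide calcium-imaging screens in larval zebrafish epilepsy
    models. Reduces atlas-registered GCaMP volumes to active supervoxels,
    computes inter-area correlation fingerprints across stimulus-defined
    activity states, clusters fingerprints to select polytherapy candidates
    by iterative cluster elimination, and scores candidate treatments for
    seizure-suppression efficacy (empirical-mode-decomposition based local
    field potential analysis) and behavioral side effects (skeleton-tracked
    locomotor features). Includes a synthetic-data generator with planted,
    recoverable ground truth so every stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
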