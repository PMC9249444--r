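Package: microbeat
Title: Micro Recurrent One-Class Ensembles for Annotated ECG Beat Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A micro-footprint classifier for annotated single-lead
    physiological signal streams (ECG heartbeats in the AAMI N/S/V grouping).
    Implements nine-scale wavelet denoising with soft universal thresholding,
    annotation-driven beat segmentation with per-slice L2 normalisation, a
    two-level windowed recurrent feature extractor with a shared window-level
    cell, and a bank of per-class one-class mini-classifiers trained with a
    negative log-likelihood plus input-gradient (H-reg) penalty and a
    parameter-space anchor, followed by a KL-barycenter shared-knowledge
    removal step. Includes a synthetic annotated ECG generator with
    controllable class separation so the full train/evaluate loop runs
    without external data, readers and writers for WFDB-style and delimited
    records, stratified 6:2:2 splitting, precision/recall/F1 evaluation, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
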