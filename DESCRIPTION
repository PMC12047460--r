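Package: ectopy
Title: Two-Stage Ventricular Ectopy Detection and Daily PVC Burden for
    Single-Lead Ambulatory ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects premature ventricular contractions (PVCs), couplets and
    triplets on single-lead ambulatory ECG with a two-stage algorithm of the
    kind used in insertable cardiac monitors: a cheap interval/amplitude
    trigger stage nominates candidate beats, and a morphology stage classifies
    each candidate with per-sequence-type logistic regression over correlation
    waveform analysis (CWA/DCWA) template-matching features.  Aggregates beat
    labels into daily PVC-burden percentages with a configurable alert
    threshold, scores detections against reference annotations (tolerance
    matching, gross / patient-average / GEE-adjusted metrics, Bland-Altman
    burden agreement), reads and writes WFDB records, and ships a fully
    annotated synthetic ECG generator so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
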