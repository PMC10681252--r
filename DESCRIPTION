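Package: totonou
Title: ERP, Band-Power and Brain-State Decoding Analysis for Sauna EEG Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying neural changes across alternating hot/cold
    sauna bathing sets from two EEG streams: scalp recordings during an auditory
    oddball task (mismatch negativity and P300 areas of the target-minus-standard
    difference waveform, reaction-time summaries) and two-channel in-ear
    recordings at rest (individual-alpha-frequency anchored band powers, and a
    spectral-feature decoder for the post-sauna "totonou" state built from PCA
    and an L1-penalised linear discriminant with cross-validated shrinkage).
    Includes zero-phase band-pass filtering, epoching and fixed-length
    segmentation with amplitude-threshold artifact rejection, mixed-design
    ANOVA with simple main effects and Holm-Bonferroni pairwise comparisons,
    and a synthetic-data generator that emulates the full study design so every
    stage is testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
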