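Package: tractlesion
Title: Tract-Lesion Overlap and Tremor-Outcome Analysis for MRgFUS Thalamotomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how focused-ultrasound thalamotomy
    lesions intersect the dentatorubrothalamic tract (DRTT) and thalamic nuclei,
    and how that intersection predicts tremor outcomes. Provides streamline
    (TCK) and label-volume (NIfTI) I/O, arc-length resampling and the minimum
    average direct-flip (MDF) streamline distance, single-pass incremental
    MDF clustering with an adaptive threshold search that isolates anterior,
    middle and posterior sub-bundles, streamline coherence filtering,
    lesion-tract transection and nucleus-overlap metrics, Clinical Rating Scale
    for Tremor (CRST) and Hand Tremor Score (HTS) computation with signed
    percent change, per-element skull-parameter summaries, two-stage
    forward-selection linear regression with nested-model ANOVA, and seeded
    synthetic generators for every input so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
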