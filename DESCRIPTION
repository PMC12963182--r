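Package: adcrev
Title: Voxel-Level ADC Threshold Analysis of Diffusion Lesion Reversal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for voxel-wise analysis of diffusion-weighted imaging (DWI)
    lesion reversal after reperfusion therapy in acute ischaemic stroke. Given a
    baseline apparent diffusion coefficient (ADC) map and co-registered
    pre-/post-treatment lesion masks, the package classifies each baseline
    lesion voxel as reversed or persistent, quantifies reversal volumes, and
    evaluates how well baseline ADC predicts voxel fate: threshold sweeps with
    sensitivity/specificity, ROC curves with trapezoidal AUC, Youden-optimal
    cutoffs, and per-ADC-band reversal probabilities. Includes patient
    eligibility filtering with flow summaries, Dice inter-rater agreement, and a
    calibrated synthetic stroke-cohort generator so that the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
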