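Package: nfcoupling
Title: Closed-Loop fMRI Neurofeedback of Inter-Regional BOLD Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, simulating and analysing correlation-based
    real-time fMRI neurofeedback experiments in which the feedback signal is
    the sliding-window Pearson correlation between two regions of interest
    (right anterior superior temporal lobe and subgenual cingulate cortex).
    Provides block-design paradigm timelines, spherical ROI construction with
    smoothing, affine warping and top-fraction voxel selection, a streaming
    feedback engine implementing increase and stabilise reinforcement rules
    with motion gating, a seed-deterministic synthetic BOLD generator
    (including a closed-loop responsive participant), and the offline trial
    statistics: per-subject standardised regression slopes, Cohen's d,
    repeated-measures ANOVA with its equivalent difference-score t-test,
    ANCOVA confirmation, minimised randomisation, and thermometer-feedback
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
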