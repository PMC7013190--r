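Package: nfconn
Title: Connectivity-Based Real-Time fMRI Neurofeedback Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing connectivity-based real-time
    fMRI neurofeedback experiments that reward the sliding-window partial
    correlation between two cortical regions (DLPFC and ACC) while controlling
    for a nuisance region. Provides block-design construction for localizer
    and neurofeedback runs, a seeded generator of ROI-mean BOLD time series
    with condition-dependent coupling, AR(1) noise and drift, localizer-based
    calibration of the feedback range, a streaming per-TR feedback engine with
    0-10 gauge scaling and yoked sham playback, offline neurofeedback-signal
    time courses, and a simplified first-level psychophysiological interaction
    (PPI) model for parameter recovery on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
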