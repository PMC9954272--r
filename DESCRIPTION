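Package: sepalert
Title: Digital Biomarkers and Screening Analytics for a Two-Minute
    Spatial Execution Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a tablet-based two-minute spatial execution process
    (SEP) screening paradigm for mild cognitive impairment (MCI) due to
    Alzheimer's disease. Reads and writes per-trial human-computer
    interaction trajectory logs (60 Hz sphere positions plus cube
    elimination events), extracts the eight time- and distance-domain SEP
    digital biomarkers (METRtotal, METfirst, ETcrossing, ETabove,
    MEDtotal, MEEfirst, EDcrossing, EDabove), simulates the paradigm with
    an inertial steered-sphere agent, generates quartile-calibrated
    synthetic cohorts via a Gaussian copula, and runs the screening
    pipeline: Kruskal-Wallis group comparison, forward (step-up) logistic
    feature selection, and ROC/AUC evaluation of single markers and their
    combination, overall and in the basic-education (>9 years) subgroup.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
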