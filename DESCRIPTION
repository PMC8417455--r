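Package: phfa
Title: Interictal High-Frequency Background Activity Biomarkers for
    Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the interictal high-frequency background activity
    (HFA) of multichannel intracranial EEG and scores channels for
    association with epileptogenic tissue.  Recordings are re-referenced
    with group-wise common average references, restricted to interictal
    time, cut into epochs, and redacted of detected high-frequency
    oscillations (HFOs) and artifacts.  Two zero-phase elliptic band-pass
    filters (30-80 Hz, 80-500 Hz) feed 19 morphology features per band
    built from rectification, line-length, curvature and Teager-Kaiser
    energy transforms.  Per-epoch features are reduced to one
    time-integrated value per channel, associated with seizure-onset-zone
    and resected-volume labels by patient-weighted logistic regression,
    and combined into a cross-validated pathological-HFA (pHFA) score via
    whitening, PCA and logistic regression under hold-out-one-patient
    cross-validation.  Includes a synthetic-cohort generator, asymmetry
    statistics with bootstrap confidence intervals, the HFO-rate x pHFA
    product biomarker, and minimal EDF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
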