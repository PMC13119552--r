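Package: ppgrhythm
Title: Multimodal Photoplethysmography Arrhythmia Detection and Reporting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for rhythm analysis of single-channel photoplethysmography
    (PPG) recordings: synthetic rhythm-labelled cohort generation with
    class-conditional RR-interval structure, peak-based segmentation and
    preprocessing to fixed-length normalized segments, time-domain heart rate
    variability features (HR, SDNN, RMSSD, pNN50), CLIP-style contrastive
    pretraining aligning waveform, clinical and rhythm-text embeddings, a
    multitask 1D U-Net for four-class rhythm classification with per-sample
    abnormal-interval segmentation, evaluation metrics, similar-patient
    retrieval and deterministic evidence-grounded report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
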