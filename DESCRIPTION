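Package: repolsig
Title: ECG Repolarization Biomarkers for Detecting Late Sodium Current Block
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for drug-induced changes in ECG
    repolarization biomarkers. Generates a synthetic five-period crossover
    trial with pharmacokinetically driven drug effects on T-wave shape,
    delineates 10-second ECGs via a median beat (QT, J-Tpeak, Tpeak-Tend),
    computes T-wave morphology biomarkers (flatness, asymmetry, amplitude,
    ERD30%/LRD30%, ventricular gradient), applies Fridericia and exponential
    heart-rate corrections with data-driven exponent estimation, fits
    placebo-corrected exposure-response mixed models, and classifies
    multichannel (hERG plus late sodium) versus selective hERG potassium
    channel block with ROC/DeLong analysis and a J-Tpeakc/QTc decision rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
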