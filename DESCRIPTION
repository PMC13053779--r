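Package: oncosensi
Title: Organoid Radiation-Sensitivity Screening and the OncoSensi Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for patient-derived organoid (PDO)
    radiosensitivity screening on 384-pillar plates irradiated with an
    automated radiation modulator (ARM). Covers dwell-time dose scheduling
    and delivery-quality statistics, thresholded green-fluorescence
    viability quantification, dose-response curves and trapezoid RT-AUC,
    frozen-reference Z-score standardisation of cohort features, a
    logistic-regression radiation-resistance index (OncoSensi), and
    validation by ROC analysis, Kaplan-Meier recurrence-free survival and
    the log-rank test. Includes synthetic plate-image and cohort
    generators so the whole pipeline is testable without raw images, and
    a bundled reference cohort of 14 test and 6 negative-validation head
    and neck cancer patients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    survival,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
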