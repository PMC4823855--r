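Package: akicode
Title: Validation of ICD-10 Acute Kidney Injury Codes Against Creatinine-Based AKIN Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to evaluate how well administrative hospital diagnosis codes
    (the ICD-10 N17x family for acute renal failure) identify acute kidney
    injury in kidney transplant recipients, against a reference standard of
    creatinine-based AKIN staging. Provides a synthetic
    administrative/laboratory data generator (distributional and
    exact-planting modes), cohort eligibility filtering with random index
    admission selection, baseline and peak creatinine selection with AKIN
    staging, diagnosis-type coding algorithms, 2x2 diagnostic accuracy
    summaries with Wilson score intervals, positive likelihood ratios and
    small-cell suppression, code-positive versus code-negative
    creatinine-change contrasts, and an oracle that reconstructs latent 2x2
    counts from printed summary statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
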