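Package: mibiquant
Title: Quantitative Dual-Time-Point Tc-99m-MIBI Thyroid Scintigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Region-of-interest quantification of dual-time-point planar
    Tc-99m-sestamibi (MIBI) thyroid scintigraphy for thyroid nodules with
    indeterminate cytology. Computes the nodular wash-out index (WOind) from
    background-subtracted mean counts and the retention index (R.I.) from
    early and delayed nodule-to-normal-tissue ratios, classifies nodules as
    suspicious or benign against published cutoffs, and evaluates diagnostic
    performance (sensitivity, specificity, accuracy, PPV, NPV with exact
    binomial confidence intervals) against histology. Ships a 20-patient
    cohort fixture, a synthetic two-lobe thyroid phantom generator with
    Poisson counting noise and closed-form noiseless index oracles, and
    planar-image / ROI-mask input-output in portable plain-text formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
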