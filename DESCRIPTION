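Package: cogchange
Title: Reliable Change Analysis for Longitudinal Neuropsychological Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cognitive change between two assessment
    sessions in clinical cohorts. Raw neuropsychological test scores are
    standardised against published norms, impairment and multivariate
    impairment base rates are classified against configurable cutoffs, and
    individual change is evaluated with regression-based reliable change
    indices (RCIs) calibrated on a paired healthy control cohort, correcting
    for practice effects and regression to the mean. Includes Monte Carlo
    chance-rate testing of impairment base rates under a correlated null,
    univariable and multivariable logistic models of decline with the usual
    diagnostics (separation detection, variance inflation factors,
    Box-Tidwell linearity checks), lesion-overlap heatmap construction from
    co-registered binary tumour masks, and a synthetic cohort generator so
    the full pipeline can be exercised and validated without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
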