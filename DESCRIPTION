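Package: normref
Title: Sample-Size and Covariate Effects in Neuroanatomical Normative Models
Version: 0.1.0
Authors@R:
    person("normref", "maintainers", email = "normref@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how the size and covariate composition of a
    reference cohort affect neuroanatomical normative models. Implements warped
    Bayesian linear regression per brain region with a sinh-arcsinh likelihood
    and cubic B-spline age basis, stratified train/test splitting, representative
    and beta-weighted age-skewed subsampling designs, sex-imbalanced draws, an
    age-bin coverage statistic, model-fit and deviation-score evaluation (MSLL,
    SMSE, EV, Rho, ICC(2,1), tail calibration, MSE/MBE of z-scores), clinical
    readouts (negative outlier flags, total outlier counts, support-vector
    classification), linear mixed-effects summarization with FDR correction,
    transfer-learning recalibration by mean-level offsets, and a seeded
    synthetic multi-site cohort generator with analytic centile oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    splines,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
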