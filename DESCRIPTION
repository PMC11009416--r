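Package: qpridge
Title: Ridge Regression for Overdispersed Quasi-Poisson Count Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quasi-likelihood estimation of the quasi-Poisson regression
    model for overdispersed count data by iteratively reweighted least
    squares, together with a ridge (shrinkage) estimator that counters
    multicollinearity among regressors. Provides sixteen data-driven rules
    for choosing the ridge biasing parameter, exact finite-sample bias,
    covariance and mean-squared-error expressions in the canonical
    (eigenvector) form, a Monte-Carlo engine for comparing estimators over
    grids of sample size, dispersion and regressor correlation, and
    multicollinearity / predictive diagnostics (condition index, PRESS from
    Pearson residuals, k-fold cross-validation). A command-line interface
    covers fitting, simulation, diagnostics and fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
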