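Package: earlygsd
Title: Group Sequential Trial Planning with Early Longitudinal Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planning and monitoring tools for two-arm group sequential trials
    whose interim analyses borrow information from early longitudinal outcomes
    correlated with the primary outcome. Provides closed-form information
    accrual curves under fixed, linearly increasing and linearly decreasing
    recruitment-rate models combined with uniform (compound-symmetry) and
    exponential (AR(1)-type) correlation structures; analytic minimum and
    maximum variance-reduction factors over early-outcome spacings; group
    sequential boundary-crossing probabilities, power and boundary solving on
    the canonical joint distribution; a generalized least squares monitoring
    estimator for monotone longitudinal data; and a seeded individual
    participant simulator that serves as a Monte Carlo check on every analytic
    formula.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
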