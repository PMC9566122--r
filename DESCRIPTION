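Package: tcarsim
Title: Synthetic Carotid Revascularization Cohorts and a Ladder of
    Time-to-Event Effect Estimators
Version: 0.9.0
Authors@R: person("TCAR", "Cohort Maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Simulates an observational cohort comparing transfemoral
    carotid artery stenting (TF-CAS) against transcarotid artery
    revascularization (TCAR) with measured and unmeasured confounding, a
    continuous treatment-preference instrument, explicit counterfactual
    event times, and right censoring under a true null treatment effect.
    Provides the full ladder of effect estimators used to analyse such
    cohorts: Kaplan-Meier contrasts (incidence difference, restricted
    mean survival time), Cox proportional-hazards regression (plain,
    weighted, robust), gamma-frailty Cox models, average (weighted)
    hazard ratios and concordance probability, propensity-score weighting
    and matching, doubly-robust weighting, the two-stage residual
    inclusion with frailty (2SRI-F) instrumental-variable algorithm, and
    a marginal structural Cox estimator with a brute-force counterfactual
    oracle.  A pipeline assembles every analysis into a single summary
    grid and a command-line interface exposes simulation, calibration,
    analysis and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
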