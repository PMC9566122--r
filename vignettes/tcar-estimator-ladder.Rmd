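---
title: "The TCAR synthetic cohort and its estimator ladder: models, calibration, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The TCAR synthetic cohort and its estimator ladder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## 1. What the package models

`tcarsim` emulates an observational comparison of two carotid
revascularization procedures — transfemoral stenting (TF-CAS, coded
`treatment = 1`) versus transcarotid revascularization (TCAR, coded 0) —
on a composite stroke-or-death outcome over 12 months of follow-up.  The
defining feature of the setting is *confounded treatment choice*: who
receives which procedure depends on measured severity, on factors nobody
recorded, and on the habits of the treating centre.  The generator makes
all three channels explicit and keeps the truth available:

* `m_score` (M): a standardized composite of measured confounders.
* `u_score` (U): a standardized unmeasured confounder.
* `z_pref` (Z): a standardized instrument — it moves treatment choice
  but never the outcome, satisfying the three instrumental-variable
  conditions by construction.

Assignment is logistic in (M, U, Z); event times are Weibull
proportional-hazards in (M, U, X).  The conditional treatment effect is
**null** (`treatment_log_hr = 0`), so every nonzero contrast the crude
analyses report is confounding bias, and an estimator is "working"
exactly to the extent that it returns to 1 (or 0, for differences).

Each subject carries both counterfactual times T0 and T1, generated from
a *single shared uniform draw* through the Weibull inverse CDF.  This
rank-preserving coupling is a design choice the data-generating story
does not force; we adopt it because it makes two downstream modes exact
rather than approximate: re-randomizing the same cohort into an emulated
RCT (`rerandomize_rct()`) needs a well-defined outcome under the
not-received arm, and under the null the coupling collapses to the
degenerate-correct `t_control == t_treated`.

Censoring is the minimum of an administrative cut at 12 months and an
exponential dropout time.  The observed data in the motivating registry
show many fewer raw events than the Kaplan–Meier event fraction implies,
i.e. substantial in-window censoring; a single exponential rate is the
simplest law reproducing that gap.  Real registries censor by staggered
entry, which is closer to uniform; we did not model that, and nothing in
the package depends on the censoring family beyond its calibrated mass.

### Parameters and defaults

| parameter | default | units / scale | role |
|---|---|---|---|
| `n_subjects` | 35,829 | subjects | registry size |
| `assignment_intercept` | −0.5226 | log-odds | arm split (≈ 40.7% TF-CAS) |
| `assignment_m`, `assignment_u` | 0.439, 0.574 | log-odds per SD | confounded selection |
| `assignment_z` | 1.19 | log-odds per SD | instrument strength (first-stage F ≈ 8,400) |
| `hazard_m`, `hazard_u` | 0.511, 0.625 | log-hazard per SD | outcome model |
| `treatment_log_hr` | 0 | log-hazard | the null truth |
| `baseline_shape` | 0.2 | — | Weibull shape |
| `baseline_scale` | 1.59e7 | months | Weibull scale |
| `admin_censor_months` | 12 | months | follow-up horizon |
| `dropout_rate` | 0.22 | per month | exponential dropout |
| `seed` | 2201 | — | shipped default draw |

`baseline_shape = 0.2` was fixed a priori on clinical grounds: the
hazard of stroke or death after carotid revascularization is strongly
front-loaded (perioperative events dominate the first month), and a
sharply decreasing Weibull hazard is the natural one-parameter
expression of that.  It is also the regime in which the survival curves
separate early, which is what makes a 12-month restricted-mean loss of a
third of a month compatible with a 3-point incidence difference.

## 2. Calibration

The registry quantities the generator must reproduce are moments of one
published dataset: the arm split, the per-arm 12-month Kaplan–Meier
event percentages, the crude Cox HR and the score-adjusted Cox HR.
`calibrate_generator()` matches them by stochastic approximation: each
iteration simulates the moments and applies closed-form damped updates
that exploit monotone parameter-moment links (intercept ↔ arm fraction
on the logit scale; Weibull scale ↔ event level through
(t/λ)^k; `hazard_u` ↔ adjusted HR through the between-arm U
imbalance; `hazard_m` ↔ the crude-vs-adjusted gap).  Infeasible target
combinations (for example a non-null crude HR requested from a
configuration with no confounding and a null effect) are rejected up
front rather than searched for.

Calibration has three modes because the published numbers are one
*draw*, not population values. `"population"` centres moments averaged
over fresh replicates; `"default-draw"` matches the single cohort drawn
with the config's own seed; the shipped defaults use `"blend"`, the
equal-weight compromise, so the default cohort reproduces the published
numbers within the stated tolerances while freshly seeded cohorts stay
centred on them.  The residual seed-to-seed scatter of every downstream
estimate is the irreducible sampling noise of a 35,829-subject draw —
the published values themselves carry that same noise.

The dropout rate was tuned separately to the published total event
count, and `assignment_z` to the published first-stage F statistic;
neither is part of the standard target set.

## 3. The estimators

**Kaplan–Meier / Nelson–Aalen** are implemented directly (weighted
product-limit and increment sums) because the weighted variants feed the
IPSW and marginal layers.  Pointwise variance is Greenwood's; interval
estimates use the complementary log-log transform, which keeps bands in
[0, 1] (the source analyses do not state their transform; this is the
common conservative choice).

**Incidence difference** at a horizon is the KM event-percentage
contrast, treated minus control, with a delta-method normal CI.

**RMST difference** integrates each arm's KM step function exactly on
[0, τ] and reports treated minus control, so event-free time *lost*
under TF-CAS is negative.  The variance is the standard restricted-mean
influence form: the squared remaining area beyond each event time times
the Greenwood increment.  The test suite checks both point estimate and
standard error against `survival`'s restricted-mean output.

**Cox regression** (`fit_cox`) maximizes the partial likelihood by
Newton–Raphson with step-halving.  Efron tie handling is the default
(standard practice; ties are measure-zero in the generator but user data
may have them).  Case weights (IPSW) and event-time weights (the wHR
below) are both supported; with either present the reported CI uses the
Lin–Wei robust sandwich built from score residuals.  Score residuals use
the Breslow form even under Efron ties — the difference vanishes without
ties.  The Breslow baseline cumulative hazard is kept on the
covariate-zero scale for the standardization steps.

**Average hazard ratio** (wHR).  The estimand is the weighted average
∫ λ1/λ0 dw(t).  The package implements the estimating-equation dialect:
each event time's score contribution is multiplied by w(t), with weights
normalized to mean one.  For the constant weight w ≡ 1 this equation *is*
the ordinary partial-likelihood score, so the crude wHR coincides with
the crude HR; user-grid weights allow genuinely time-weighted averages,
and the tests validate the solver against an independently coded
root-finder.  The concordance probability is the monotone transform
AHR/(1+AHR).

**Kernel hazard curves** smooth Nelson–Aalen increments with an
Epanechnikov kernel (default bandwidth 1.5 months) and reflection
boundary correction at 0 and at the follow-up end — without reflection
the front-loaded hazard would be halved at the origin.

**Propensity layer.**  The propensity model is logistic (IRLS via
`stats::glm`) on *measured* covariates only; `u_score` is refused by
contract.  IPSW weights are 1/p and 1/(1−p), optionally stabilized.
Matching is greedy 1:1 nearest-neighbour on the logit score without
replacement, treated subjects in seeded random order, caliper 0.2 SD of
the logit score (the common convention; the source gives none, so the
published pair count is a qualitative check only).  The doubly robust
variant runs the IPSW-weighted Cox with the propensity covariates also
in the outcome model.

**2SRI-F.**  Stage 1 is an *ordinary least squares* regression of the
binary treatment on measured covariates plus the instrument — linear by
design, because the residuals (not fitted probabilities) are what carry
unmeasured-confounder information.  Stage 2 is a gamma-frailty Cox model
on treatment, measured covariates, the stage-1 residuals and an
individual frailty that absorbs the white noise residual inclusion
injects.  A first-stage F below 10 (conventional bound, configurable)
attaches a prominent weak-instrument warning.  Because treatment and its
own first-stage residuals are strongly collinear, the 2SRI-F treatment
coefficient has a several-fold larger sampling sd than the adjusted Cox
coefficient — visible in the wide CIs, and the reason the package's
replicate-based tests compare means rather than single draws.

**Gamma-frailty Cox** is estimated by EM using gamma conjugacy: the
E-step posterior frailty for subject i is
(1/θ + δi)/(1/θ + Λ̂(Yi)·exp(xiβ)); the M-step is a Cox fit with log
posterior frailties as offset.  θ itself maximizes the gamma-integrated
marginal likelihood, profiled by golden-section search on [0, 10] to a
bracket of 1e−4, warm-starting each EM from the previous θ's solution.
θ = 0 reproduces the plain Cox fit exactly; individual-level frailty
variance is weakly identified, so agreement with the established
penalized-likelihood implementation is asserted within that weak
identification, not to machine precision.

**Marginal structural Cox.**  The estimand is the population-level ψ in
λ1(t) = λ0(t)·e^ψ, where both hazards refer to counterfactual
populations.  The cited estimators for this model live in other papers'
appendices; the package therefore defines *one* principled estimator and
validates it against ground truth rather than against those internals:
dichotomize the instrument at the median, model treatment on the
dichotomized instrument (optionally with measured covariates), weight
subjects by the inverse modelled probability of their received arm, form
weighted arm-wise cumulative hazards, and take ψ as the least-squares
constant separating the two log cumulative hazards over the shared event
grid, with a subject-level percentile bootstrap CI (default 500
resamples).  A third weighting label, `"trivial"` (unit weights), covers
randomized data, where the instrument is unrelated to the re-randomized
treatment and the weighted construction would rightly refuse to run.
`true_marginal_psi()` is the corresponding oracle: simulate a large
uncensored counterfactual population and fit the same log-cumulative-
hazard relation, reporting how constant the pointwise difference
actually is (with covariates in the hazard the marginal model holds only
approximately — that non-constancy is itself the non-collapsibility
phenomenon).  The tests require the estimator to recover the oracle ψ
and to respect the strict ordering 1 < e^ψ < conditional HR when an
independent prognostic factor is present.

## 4. Numerical choices

* Newton–Raphson stops at gradient max-norm < 1e−9, or when the Newton
  step falls below 1e−11 (double-precision noise at n ≈ 36,000); failure
  to meet either within 30 iterations flags the fit rather than erroring.
* Step-halving (up to 20 halvings) guards against overshoot; monotone
  likelihood (|β| > 15) raises a warning naming the suspicion.
* Covariates are centred internally; the baseline hazard is rescaled
  back to the covariate-zero scale on output.
* Standardized survival curves average subject-level predictions on an
  event-time grid thinned to ≤ 250 points — an O(n·grid) memory bound.
* The instrument-relatedness guard in the marginal estimator is a 3-SE
  test on the arm-probability split (or the model z-value), not a fixed
  probability gap, so it scales with n.
* Degenerate inputs have defined behaviour: zero-subject cohorts are
  schema-valid; all-censored data error with "no events"; an empty
  matching arm errors; a caliper of numerical width zero with identical
  scores still matches (distance 0 ≤ caliper).
* All randomness flows through explicit seeds; the generator saves and
  restores the caller's RNG state, and derived sub-seeds stay below
  2^31.

## 5. What a green test does and does not establish

The generator reproduces the published *moments* of one registry
comparison under a smooth parametric law.  It does not reproduce the
original data row-for-row (the published generation process included
undocumented manual edits and is explicitly not a single parametric
model), does not model named clinical covariates individually, has no
competing risks (the composite outcome is a single event), no staggered
entry, no time-varying effects, and its instrument is cleanly valid by
construction — real centre-preference instruments never are.  A green
acceptance suite therefore establishes that the estimator ladder behaves
correctly *in a world with the published data's first-order structure*,
not that any clinical conclusion transfers.  Conversely, the estimators
themselves are generator-agnostic: every analysis function accepts any
subject-level survival table in the documented CSV dialect.

## 6. Known limitations

* The 2SRI-F sampling sd at the default n is comparable to the width of
  the published-value tolerance bands, so single-seed comparisons of
  that cell are intrinsically fragile (the test suite says so where it
  matters).
* The frailty profile likelihood is assumed unimodal on [0, 10] for the
  golden-section search; pathological multimodality would be silently
  resolved to one mode (the boundary cases θ → 0 and θ → 10 are
  flagged).
* The marginal estimator's weights come from the instrument only; under
  strong *measured* confounding with `weighting = "none"` it inherits
  that bias by design, mirroring the corresponding published analyses.
* `read_cohort_csv()` does not persist provenance or configuration;
  round-tripping a cohort keeps the data but drops the generator
  metadata.
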