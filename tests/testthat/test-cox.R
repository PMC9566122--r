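library(survival)

test_that("partial likelihood equals hand enumeration on tiny data", {
  x <- cbind(z = c(0.5, -1, 2, 0, 1.5, -0.3))
  tt <- c(3, 1, 4, 6, 2, 5)
  st <- c(1, 0, 1, 1, 1, 0)
  fit <- fit_cox(x, tt, st, ties = "breslow")
  # loglik at the fitted value, by naive enumeration over risk sets
  expect_equal(fit$loglik, enum_partial_loglik(fit$coefficients, x, tt, st),
               tolerance = 1e-10)
  # the fitted beta maximizes the enumerated likelihood
  opt <- optimize(function(b) enum_partial_loglik(b, x, tt, st),
                  c(-5, 5), maximum = TRUE)
  expect_equal(unname(fit$coefficients), opt$maximum, tolerance = 1e-4)
})

test_that("large-sample two-group fit recovers HR 2 and matches coxph", {
  d <- exp_two_arm(5000, 0.1, 0.2, seed = 21)
  fit <- fit_cox(cbind(treatment = d$treatment), d$observed_time, d$status)
  expect_equal(unname(exp(fit$coefficients)), 2, tolerance = 0.08)
  ref <- coxph(Surv(observed_time, status) ~ treatment, data = d,
               ties = "efron")
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$covariance))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-6)
})

test_that("tied data: Efron and Breslow both match coxph; equal when no ties", {
  d <- exp_two_arm(400, 0.15, 0.3, cens_max = 12, seed = 31)
  d$observed_time <- ceiling(d$observed_time * 2) / 2   # force ties
  X <- cbind(treatment = d$treatment)
  for (tie in c("efron", "breslow")) {
    fit <- fit_cox(X, d$observed_time, d$status, ties = tie)
    ref <- coxph(Surv(observed_time, status) ~ treatment, data = d,
                 ties = tie)
    expect_equal(unname(fit$coefficients), unname(coef(ref)),
                 tolerance = 1e-7)
  }
  u <- exp_two_arm(300, 0.15, 0.3, seed = 32)        # continuous: no ties
  fe <- fit_cox(cbind(t = u$treatment), u$observed_time, u$status,
                ties = "efron")
  fb <- fit_cox(cbind(t = u$treatment), u$observed_time, u$status,
                ties = "breslow")
  expect_identical(fe$coefficients, fb$coefficients)
})

test_that("weights: constant weights do not move the estimate; robust matches coxph", {
  d <- exp_two_arm(800, 0.1, 0.18, cens_max = 15, seed = 41)
  X <- cbind(treatment = d$treatment)
  f1 <- fit_cox(X, d$observed_time, d$status)
  f7 <- fit_cox(X, d$observed_time, d$status, weights = rep(7, nrow(d)))
  expect_equal(f1$coefficients, f7$coefficients, tolerance = 1e-9)

  w <- tcarsim:::with_seed(42, runif(nrow(d), 0.5, 3))
  fw <- fit_cox(X, d$observed_time, d$status, weights = w)
  ref <- coxph(Surv(observed_time, status) ~ treatment, data = d,
               weights = w, robust = TRUE)
  expect_equal(unname(fw$coefficients), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(sqrt(diag(fw$robust_covariance))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
})

test_that("score, baseline and interval invariants", {
  d <- exp_two_arm(500, 0.12, 0.2, cens_max = 12, seed = 51)
  X <- cbind(treatment = d$treatment,
             noise = tcarsim:::with_seed(52, rnorm(nrow(d))))
  fit <- fit_cox(X, d$observed_time, d$status)
  expect_true(fit$converged)
  expect_lt(fit$engine$grad_max, 1e-8)
  expect_gte(fit$loglik, fit$loglik_null)
  bh <- basehaz(coxph(Surv(d$observed_time, d$status) ~ X, ties = "efron"),
                centered = FALSE)
  expect_equal(curve_eval(fit$baseline_cumhaz, bh$time), bh$hazard,
               tolerance = 1e-6)
  s <- cox_hr(fit, "treatment")
  expect_true(s$ci_low <= s$estimate && s$estimate <= s$ci_high)
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(fit_cox(cbind(a = rep(1, 5)), 1:5, c(1, 0, 1, 0, 1)),
               "constant covariate")
  expect_error(fit_cox(cbind(a = rnorm(5)), 1:5, rep(0, 5)), "no events")
  # perfect separation: all events in one arm, monotone likelihood
  x <- cbind(g = rep(c(0, 1), each = 10))
  tt <- c(1:10, 21:30)
  st <- rep(c(1, 0), each = 10)
  expect_warning(fit_cox(x, tt, st, max_iter = 60), "monotone|converge")
})

test_that("omitting an independent prognostic covariate attenuates the HR", {
  # the non-collapsibility phenomenon: true conditional HR 2, U ~ N(0,1)
  # independent of treatment with log-hazard 1.2; the marginal Cox HR is
  # strictly between 1 and 2
  cfg <- generator_config(n_subjects = 3000, assignment_intercept = 0,
                          assignment_m = 0, assignment_u = 0,
                          assignment_z = 0.01, hazard_m = 0,
                          hazard_u = 1.2, treatment_log_hr = log(2),
                          baseline_scale = 60, baseline_shape = 1,
                          dropout_rate = 0)
  reps <- t(vapply(1:50, function(r) {
    co <- generate_cohort(cfg, seed = 700 + r)
    omit <- fit_cox(cbind(treatment = co$treatment), co$observed_time,
                    co$status)$coefficients[["treatment"]]
    full <- fit_cox(cbind(treatment = co$treatment, u = co$u_score),
                    co$observed_time, co$status)$coefficients[["treatment"]]
    c(omit, full)
  }, numeric(2)))
  expect_gt(mean(reps[, 1]), log(1.15))
  expect_lt(mean(reps[, 1]), log(2) - 0.03)     # strictly attenuated
  expect_equal(mean(reps[, 2]), log(2), tolerance = 0.04)
})
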