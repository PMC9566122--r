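test_that("propensity model: saturated 2x2 case matches cell fractions", {
  # binary covariate with known counts: logistic MLE is saturated
  d <- data.frame(
    treatment = rep(c(1, 0, 1, 0), c(30, 70, 60, 40)),
    g = rep(c(0, 0, 1, 1), c(30, 70, 60, 40)))
  ps <- fit_propensity(d, "g")
  expect_equal(unique(ps$scores[d$g == 0]), 0.3, tolerance = 1e-9)
  expect_equal(unique(ps$scores[d$g == 1]), 0.6, tolerance = 1e-9)
})

test_that("uninformative covariate yields flat scores and unchanged KM", {
  d <- exp_two_arm(800, 0.1, 0.1, cens_max = 12, seed = 101)
  d$noise <- tcarsim:::with_seed(102, rnorm(nrow(d)))
  ps <- fit_propensity(d, "noise")
  expect_lt(diff(range(ps$scores)), 0.1)
  kmw <- kaplan_meier(d$observed_time, d$status, ps$weights)
  km <- kaplan_meier(d$observed_time, d$status)
  expect_lt(max(abs(curve_eval(kmw, 1:10) - curve_eval(km, 1:10))), 0.02)
  expect_error(fit_propensity(d, c("noise", "u_score")), "missing columns")
  expect_error(fit_propensity(transform(d, u_score = 1), "u_score"),
               "unmeasured")
})

test_that("perfect separation is reported", {
  d <- data.frame(treatment = rep(c(0, 1), each = 20),
                  g = c(rnorm(20, -4), rnorm(20, 4)))
  expect_error(fit_propensity(d, "g"), "separation")
})

test_that("matching: identical scores, caliper behaviour, reproducibility", {
  d <- data.frame(treatment = rep(c(1, 0), c(5, 9)), g = rep(0.5, 14))
  d$g <- d$g + rep(0, 14)
  ps <- list(scores = rep(0.4, 14), treatment = d$treatment)
  m <- match_nearest(ps, caliper = 0.2, seed = 1)
  expect_identical(nrow(m$pairs), 5L)           # all of the smaller arm

  set.seed(3)
  ps2 <- list(scores = plogis(rnorm(200)), treatment = rep(c(1, 0), 100))
  m1 <- match_nearest(ps2, caliper = 0.2, seed = 9)
  m2 <- match_nearest(ps2, caliper = 0.2, seed = 9)
  expect_identical(m1$pairs, m2$pairs)
  # pair uniqueness
  expect_false(anyDuplicated(m1$pairs$treated_id) > 0)
  expect_false(anyDuplicated(m1$pairs$control_id) > 0)
  expect_true(all(m1$pairs$distance <= m1$caliper_abs + 1e-12))

  tiny <- match_nearest(ps2, caliper = 1e-9, seed = 9)
  expect_identical(nrow(tiny$pairs), 0L)
  expect_error(match_nearest(list(scores = 0.5, treatment = 1), 0.2),
               "non-empty")
})

test_that("IPSW balances the measured score on the default cohort", {
  co <- default_cohort_cached()
  raw <- standardized_mean_difference(co$m_score, co$treatment)
  ps <- fit_propensity(co, "m_score")
  bal <- standardized_mean_difference(co$m_score, co$treatment, ps$weights)
  expect_gt(abs(raw), 0.1)
  expect_lt(abs(bal), 0.05)
  # stabilized weights sum to the arm sizes within 2%
  pss <- fit_propensity(co, "m_score", stabilized = TRUE)
  s1 <- sum(pss$weights[co$treatment == 1])
  s0 <- sum(pss$weights[co$treatment == 0])
  expect_lt(abs(s1 / sum(co$treatment) - 1), 0.02)
  expect_lt(abs(s0 / sum(1 - co$treatment) - 1), 0.02)
})

test_that("doubly-robust weighting: degenerate and no-confounding limits", {
  d <- exp_two_arm(700, 0.12, 0.2, cens_max = 12, seed = 111)
  d$m_score <- tcarsim:::with_seed(112, rnorm(nrow(d)))
  # covariate unrelated to treatment: weights are ~constant, so DR equals
  # the adjusted Cox to high accuracy
  dr <- dr_ipsw_cox(d, "m_score")
  adj <- fit_cox(cbind(treatment = d$treatment, m_score = d$m_score),
                 d$observed_time, d$status)
  expect_equal(log(dr$summary$estimate),
               unname(adj$coefficients[["treatment"]]), tolerance = 0.02)

  # no measured confounding in the generator: crude, IPSW and DR agree
  cfg <- generator_config(n_subjects = 12000, assignment_m = 0)
  co <- generate_cohort(cfg, seed = 115)
  crude <- fit_cox(cbind(treatment = co$treatment), co$observed_time,
                   co$status)$coefficients[["treatment"]]
  ps <- fit_propensity(co, "m_score")
  ipsw <- fit_cox(cbind(treatment = co$treatment), co$observed_time,
                  co$status, weights = ps$weights)$coefficients[["treatment"]]
  dr2 <- log(dr_ipsw_cox(co, "m_score")$summary$estimate)
  expect_equal(ipsw, crude, tolerance = 0.05)
  expect_equal(dr2, crude, tolerance = 0.06)
})
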