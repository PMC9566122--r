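test_that("generation is deterministic and schema-valid", {
  cfg <- generator_config(n_subjects = 500)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a),
                         as.data.frame(generate_cohort(cfg, seed = 99))))

  expect_setequal(unique(a$treatment), c(0L, 1L))
  expect_false(anyDuplicated(a$subject_id) > 0)
  expect_identical(attr(a, "provenance"), "observational")

  empty <- generate_cohort(generator_config(n_subjects = 0))
  expect_s3_class(empty, "tcar_cohort")
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("m_score", "observed_time", "status") %in% names(empty)))
})

test_that("record-level invariants hold", {
  cfg <- generator_config(n_subjects = 2000)
  co <- generate_cohort(cfg)
  own <- ifelse(co$treatment == 1, co$t_treated, co$t_control)
  expect_equal(co$observed_time, pmin(own, co$censor_time))
  expect_identical(co$status, as.integer(own <= co$censor_time))
  expect_true(all(co$observed_time <= cfg$admin_censor_months + 1e-12))
  # null coupling: shared latent draw makes the counterfactual pair equal
  expect_identical(co$t_control, co$t_treated)

  cfg2 <- generator_config(n_subjects = 500, treatment_log_hr = log(2))
  co2 <- generate_cohort(cfg2)
  expect_true(all(co2$t_treated < co2$t_control))
})

test_that("config validation rejects bad values", {
  expect_error(generator_config(baseline_scale = -1), "positive")
  expect_error(generator_config(admin_censor_months = 0), "positive")
  expect_error(generator_config(hazard_m = NaN), "non-finite")
  expect_error(generator_config(n_subjects = -5), ">= 0")
})

test_that("no confounding and no effect gives a null crude HR", {
  cfg <- generator_config(n_subjects = 20000, assignment_m = 0,
                          assignment_u = 0, hazard_m = 0, hazard_u = 0,
                          treatment_log_hr = 0)
  co <- generate_cohort(cfg, seed = 7)
  fit <- fit_cox(cbind(treatment = co$treatment), co$observed_time,
                 co$status)
  se <- sqrt(fit$covariance[1, 1])
  expect_lt(abs(fit$coefficients[["treatment"]]), 3 * se)
})

test_that("confounding direction: crude HR > M-adjusted HR > 1 on average", {
  cfg <- generator_config(n_subjects = 5000)
  reps <- t(vapply(1:50, function(r) {
    co <- generate_cohort(cfg, seed = 600 + r)
    crude <- fit_cox(cbind(treatment = co$treatment), co$observed_time,
                     co$status)$coefficients[["treatment"]]
    adj <- fit_cox(cbind(treatment = co$treatment, m_score = co$m_score),
                   co$observed_time, co$status)$coefficients[["treatment"]]
    c(crude, adj)
  }, numeric(2)))
  expect_gt(mean(reps[, 1]), mean(reps[, 2]))
  expect_gt(mean(reps[, 2]), 0)
})

test_that("event fraction responds monotonically to scale and dropout", {
  base <- generator_config(n_subjects = 8000)
  frac <- function(cfg) mean(generate_cohort(cfg, seed = 11)$status)
  harder <- base; harder$baseline_scale <- base$baseline_scale / 50
  expect_gt(frac(harder), frac(base))
  retained <- base; retained$dropout_rate <- 0
  expect_gt(frac(retained), frac(base))
})

test_that("RCT re-randomization recomputes outcomes and is reproducible", {
  co <- generate_cohort(generator_config(n_subjects = 6000))
  r1 <- rerandomize_rct(co, 0.5, seed = 3)
  r2 <- rerandomize_rct(co, 0.5, seed = 3)
  expect_identical(r1$treatment, r2$treatment)
  expect_identical(attr(r1, "provenance"), "rct")
  # binomial noise around n/2
  expect_lt(abs(sum(r1$treatment) - 3000), 4 * sqrt(6000 * 0.25))
  own <- ifelse(r1$treatment == 1, r1$t_treated, r1$t_control)
  expect_equal(r1$observed_time, pmin(own, r1$censor_time))
  # re-randomization must be independent of the covariates
  expect_lt(abs(cor(r1$treatment, r1$u_score)), 0.05)

  no_cf <- as.data.frame(co)[c("subject_id", "observed_time", "status")]
  expect_error(rerandomize_rct(no_cf), "missing columns")
})

test_that("null-effect RCT replications cover HR = 1 at the nominal rate", {
  co <- generate_cohort(generator_config(n_subjects = 4000))
  covered <- vapply(1:100, function(r) {
    rct <- rerandomize_rct(co, 0.5, seed = 100 + r)
    s <- cox_hr(fit_cox(cbind(treatment = rct$treatment),
                        rct$observed_time, rct$status))
    s$ci_low <= 1 && 1 <= s$ci_high
  }, logical(1))
  # ~95 of 100 expected; re-randomizations share one cohort so allow slack
  expect_gte(sum(covered), 85)
})

test_that("config and cohort serialization round-trip losslessly", {
  cfg <- generator_config(n_subjects = 123, hazard_u = 0.3210987654321)
  f <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(unclass(back), unclass(cfg), tolerance = 0)

  co <- generate_cohort(generator_config(n_subjects = 50))
  g <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, g)
  back2 <- read_cohort_csv(g)
  expect_equal(as.data.frame(back2), as.data.frame(co), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("calibration: fixed point returns, infeasible targets refused", {
  cfg <- generator_config(n_subjects = 20000)
  mom <- simulated_moments(cfg, n_reps = 2, seed = 5)
  targets <- mom[c("arm_fraction", "crude_hr")]
  out <- calibrate_generator(cfg, targets, n_reps = 2, seed = 5,
                             max_iter = 4)
  expect_true(attr(out, "converged"))
  ach <- attr(out, "achieved")
  expect_lt(abs(ach[["arm_fraction"]] - targets[["arm_fraction"]]), 0.01)

  off <- generator_config(assignment_m = 0, assignment_u = 0, hazard_m = 0,
                          hazard_u = 0)
  expect_error(calibrate_generator(off, c(crude_hr = 1.57), max_iter = 2),
               "infeasible")
  expect_error(calibrate_generator(cfg, c(nonsense = 1)), "named")
})
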