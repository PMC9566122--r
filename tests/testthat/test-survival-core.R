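library(survival)

test_that("Kaplan-Meier matches the hand product-limit on tiny data", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$jump_times, c(1, 2, 3))
  expect_equal(km$values, c(2 / 3, 1 / 3, 0))

  # censoring between events: S(1)=3/4, then risk set of 2 at t=3
  km2 <- kaplan_meier(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(km2$values, c(3 / 4, 3 / 4 * 1 / 2))

  # no events: survival identically 1
  km3 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_length(km3$jump_times, 0)
  expect_equal(curve_eval(km3, c(0, 2, 10)), c(1, 1, 1))
})

test_that("KM and Nelson-Aalen agree with survival::survfit", {
  d <- exp_two_arm(300, 0.15, 0.15, cens_max = 10, seed = 4)
  sf <- survfit(Surv(observed_time, status) ~ 1, data = d)
  km <- kaplan_meier(d$observed_time, d$status)
  ev <- sf$n.event > 0
  expect_equal(km$jump_times, sf$time[ev])
  expect_equal(km$values, sf$surv[ev], tolerance = 1e-12)
  expect_equal(sqrt(km$pointwise_variance), (sf$std.err * sf$surv)[ev],
               tolerance = 1e-10)
  na <- nelson_aalen(d$observed_time, d$status)
  expect_equal(na$values, cumsum(sf$n.event / sf$n.risk)[ev],
               tolerance = 1e-12)
})

test_that("KM properties: empirical equivalence, weight invariance", {
  tt <- rexp(200, 0.2)
  km <- kaplan_meier(tt, rep(1, 200))
  # no censoring: KM equals the empirical survival function
  expect_equal(curve_eval(km, sort(tt)), 1 - seq_len(200) / 200,
               tolerance = 1e-12)
  d <- exp_two_arm(150, 0.2, 0.2, cens_max = 8, seed = 9)
  kmw <- kaplan_meier(d$observed_time, d$status, rep(7, nrow(d)))
  km1 <- kaplan_meier(d$observed_time, d$status)
  expect_equal(kmw$values, km1$values, tolerance = 1e-12)
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "negative")
  expect_error(kaplan_meier(c(1, 2), c(1, 1), c(-1, 1)), "negative")
})

test_that("incidence difference: symmetry, horizon validation", {
  d <- exp_two_arm(400, 0.1, 0.1, cens_max = 20, seed = 6)
  both <- rbind(transform(d, treatment = 0), transform(d, treatment = 1))
  id <- incidence_difference(both, 5)
  expect_equal(id$estimate, 0, tolerance = 1e-12)
  expect_identical(id$units, "percentage points")
  expect_error(incidence_difference(d, 1e6), "beyond the last")
})

test_that("RMST difference: closed-form step integral and sign convention", {
  # hand case: treated events at 1, 3; control events at 2, 4 (no censoring)
  d <- data.frame(treatment = c(1, 1, 0, 0), observed_time = c(1, 3, 2, 4),
                  status = 1L)
  r <- rmst_difference(d, 3)
  # treated: 1*1 + 0.5*2 = 2 ; control: 1*2 + 0.5*1 = 2.5
  expect_equal(r$estimate, 2 - 2.5, tolerance = 1e-12)
  expect_identical(r$units, "months")
  expect_lte(abs(r$estimate), 3)
  expect_error(rmst_difference(d, 3.5), "achievable maximum")

  dd <- exp_two_arm(1500, 0.12, 0.12, cens_max = 15, seed = 2)
  r2 <- rmst_difference(dd, 8)
  expect_lt(abs(r2$estimate), 0.3)   # identical laws: near zero
})

test_that("RMST arm variance matches survival's restricted mean", {
  d <- exp_two_arm(400, 0.2, 0.35, cens_max = 10, seed = 12)
  sf <- survfit(Surv(observed_time, status) ~ treatment, data = d)
  tab <- summary(sf, rmean = 6)$table
  ours1 <- tcarsim:::rmst_arm(d$observed_time[d$treatment == 1],
                              d$status[d$treatment == 1],
                              rep(1, sum(d$treatment == 1)), 6)
  ours0 <- tcarsim:::rmst_arm(d$observed_time[d$treatment == 0],
                              d$status[d$treatment == 0],
                              rep(1, sum(d$treatment == 0)), 6)
  expect_equal(ours0$rmst, unname(tab[1, "rmean"]), tolerance = 1e-8)
  expect_equal(ours1$rmst, unname(tab[2, "rmean"]), tolerance = 1e-8)
  expect_equal(sqrt(ours0$var), unname(tab[1, "se(rmean)"]),
               tolerance = 1e-6)
  expect_equal(sqrt(ours1$var), unname(tab[2, "se(rmean)"]),
               tolerance = 1e-6)
})

test_that("kernel hazard recovers a constant hazard and degenerate cases", {
  tt <- tcarsim:::with_seed(5, rexp(20000, 0.1))
  cens <- pmin(tt, 30)
  st <- as.integer(tt <= 30)
  kh <- kernel_hazard(cens, st, bandwidth = 2, grid = c(8, 10, 12),
                      tmax = 30)
  expect_equal(kh$hazard, rep(0.1, 3), tolerance = 0.05)

  expect_equal(kernel_hazard(c(1, 2), c(0, 0), grid = c(0.5, 1))$hazard,
               c(0, 0))
  expect_error(kernel_hazard(c(1, 2), c(1, 1), bandwidth = 0), "positive")
  expect_error(kernel_hazard(c(1, 2), c(1, 1), grid = numeric(0)), "empty")

  # integral of the smooth estimate over an interior window matches the
  # Nelson-Aalen increment over the same window
  grid <- seq(3, 27, by = 0.05)
  kh2 <- kernel_hazard(cens, st, bandwidth = 2, grid = grid, tmax = 30)
  na <- nelson_aalen(cens, st)
  increment <- curve_eval(na, 27) - curve_eval(na, 3)
  expect_equal(sum(kh2$hazard) * 0.05, increment, tolerance = 0.05)
})

test_that("step curves validate and export", {
  expect_error(step_curve(c(2, 1), c(0.5, 0.4)), "ascending")
  expect_error(step_curve(c(1, 2), c(0.4, 0.5)), "nonincreasing")
  expect_error(step_curve(c(1, 2), c(0.5, 0.4), type = "cumhaz"),
               "nondecreasing")
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 0, 1))
  tab <- curve_as_table(km)
  expect_named(tab, c("time", "estimate", "var", "ci_low", "ci_high",
                      "n_risk"))
  ok <- tab$estimate > 0 & tab$estimate < 1
  expect_true(all(tab$ci_low[ok] >= 0 & tab$ci_high[ok] <= 1))
  expect_true(all(tab$ci_low <= tab$estimate & tab$estimate <= tab$ci_high,
                  na.rm = TRUE))
})
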