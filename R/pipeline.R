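#' Oracle analyses using the unmeasured covariate and counterfactual times
#'
#' Analyses that are unreachable in practice but available on synthetic
#' data: Cox regression including both the measured and the unmeasured
#' confounder, the average hazard ratio adjusted for both, the RMST from
#' regression-standardized curves, and the two counterfactual Kaplan-Meier
#' curves (everyone treated / everyone control, censoring applied from the
#' stored censoring times).
#'
#' @param cohort A cohort carrying `u_score`, `t_control`, `t_treated`.
#' @param level Confidence level.
#' @return List: `cox_hr` (treatment HR given M and U), `whr`, `rmst`,
#'   `counterfactual_curves` (list of survival [step_curve()]s).
#' @export
oracle_analyses <- function(cohort, level = 0.95) {
  df <- cohort_columns(cohort, c("observed_time", "status", "treatment",
                                 "m_score", "u_score", "t_control",
                                 "t_treated", "censor_time"))
  X <- cbind(treatment = df$treatment, m_score = df$m_score,
             u_score = df$u_score)
  fit <- fit_cox(X, df$observed_time, df$status)
  whr <- average_hazard_ratio(df, covariates = c("m_score", "u_score"),
                              level = level)
  rmst <- standardized_rmst(fit, X, horizon = min(12, max(df$observed_time)),
                            level = level)
  cf <- lapply(c("t_control", "t_treated"), function(col) {
    tt <- pmin(df[[col]], df$censor_time)
    st <- as.integer(df[[col]] <= df$censor_time)
    kaplan_meier(tt, st)
  })
  names(cf) <- c("all_control", "all_treated")
  list(cox_hr = cox_hr(fit, "treatment", level = level), whr = whr$summary,
       rmst = rmst, counterfactual_curves = cf)
}

# RMST difference from regression standardization of a Cox fit: average the
# predicted curves over subjects with treatment set to 0/1, integrate the
# difference.  CI by normal approximation through the delta method on the
# treatment coefficient (the dominant source of variance).
standardized_rmst <- function(fit, X, horizon, level = 0.95) {
  base <- fit$baseline_cumhaz
  gi <- unique(round(seq(1, length(base$jump_times),
                         length.out = min(250L, length(base$jump_times)))))
  grid_t <- base$jump_times[gi]
  grid_l <- base$values[gi]
  b <- fit$coefficients
  other <- setdiff(names(b), "treatment")
  lp_other <- drop(X[, other, drop = FALSE] %*% b[other])
  area <- function(bx) {
    risk <- exp(lp_other + bx)
    surv <- colMeans(exp(-outer(risk, grid_l)))
    curve_integral(step_curve(grid_t, pmin(cummin(surv), 1),
                              type = "survival"), horizon)
  }
  bt <- b["treatment"]
  est <- area(bt) - area(0)
  se_b <- sqrt(diag(fit$covariance))["treatment"]
  slope <- (area(bt + 1e-4) - area(bt - 1e-4)) / 2e-4
  se <- abs(slope) * se_b
  z <- stats::qnorm(1 - (1 - level) / 2)
  effect_summary("RMST", est, est - z * se, est + z * se, level,
                 units = "months")
}

#' Run the complete analysis ladder on one simulated cohort
#'
#' Generates (or accepts) the cohort and fills the full summary grid:
#' measures ID, HR, wHR, RMST and mHR across the scenarios crude,
#' measured_matched (propensity matching), measured_adjusted (covariate
#' adjustment / DR weighting), omitted (2SRI-F and IV-adjusted curves),
#' rct (re-randomized trial) and oracle (unmeasured covariate revealed —
#' an extension column beyond the usual five).  Cells that are undefined
#' for a scenario stay empty.  Any stage failure is recorded in its cell
#' and the run continues.
#'
#' @param config A [generator_config()].
#' @param cohort Optionally a pre-generated cohort (config then only
#'   documents provenance).
#' @param n_boot Bootstrap resamples for the marginal estimator.
#' @param seed Seed driving re-randomization and bootstrap streams.
#' @param horizon Contrast horizon in months.
#' @param verbose Emit progress messages.
#' @return An `analysis_grid`: list with `cells` (measure x scenario list
#'   of [effect_summary()] or `NULL` or error message), `extras`
#'   (F statistic, frailty variance, matched pairs, DR HR, curves), and
#'   `meta`.
#' @export
run_full_study <- function(config = generator_config(), cohort = NULL,
                           n_boot = 200L, seed = config$seed,
                           horizon = 12, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(cohort)) {
    say("generating cohort (n = %d)", config$n_subjects)
    cohort <- generate_cohort(config, seed = seed)
  }
  horizon <- min(horizon, max(cohort$observed_time))
  measures <- c("ID", "HR", "wHR", "RMST", "mHR")
  scenarios <- c("crude", "measured_matched", "measured_adjusted",
                 "omitted", "rct", "oracle")
  cells <- stats::setNames(
    rep(list(stats::setNames(vector("list", length(measures)), measures)),
        length(scenarios)), scenarios)
  extras <- list()
  put <- function(scenario, measure, expr) {
    cells[[scenario]][[measure]] <<- tryCatch(expr, error = function(e) {
      structure(conditionMessage(e), class = "analysis_error")
    })
    invisible(NULL)
  }

  say("crude analyses")
  put("crude", "ID", incidence_difference(cohort, horizon))
  put("crude", "HR", cox_hr(fit_cox(cbind(treatment = cohort$treatment),
                                    cohort$observed_time, cohort$status)))
  put("crude", "wHR", average_hazard_ratio(cohort)$summary)
  put("crude", "RMST", rmst_difference(cohort, horizon))
  put("crude", "mHR", estimate_marginal_psi(cohort, weighting = "none",
                                            n_boot = n_boot,
                                            seed = derive_seed(seed, 11L))$hr)

  say("measured-covariate analyses")
  ps <- tryCatch(fit_propensity(cohort, "m_score"), error = function(e) e)
  if (!inherits(ps, "error")) {
    extras$ipsw_hr <- tryCatch(
      cox_hr(fit_cox(cbind(treatment = cohort$treatment),
                     cohort$observed_time, cohort$status,
                     weights = ps$weights)),
      error = function(e) conditionMessage(e))
    ms <- tryCatch(match_nearest(ps, seed = derive_seed(seed, 12L)),
                   error = function(e) e)
    if (!inherits(ms, "error")) {
      extras$n_pairs <- nrow(ms$pairs)
      mco <- matched_cohort(cohort, ms)
      put("measured_matched", "ID", incidence_difference(mco, horizon))
      put("measured_matched", "HR",
          cox_hr(fit_cox(cbind(treatment = mco$treatment),
                         mco$observed_time, mco$status)))
      put("measured_matched", "wHR", average_hazard_ratio(mco)$summary)
      put("measured_matched", "RMST", rmst_difference(mco, horizon))
    }
  }
  put("measured_matched", "mHR",
      estimate_marginal_psi(cohort, weighting = "measured", n_boot = n_boot,
                            seed = derive_seed(seed, 13L))$hr)
  adj <- tryCatch(fit_cox(cbind(treatment = cohort$treatment,
                                m_score = cohort$m_score),
                          cohort$observed_time, cohort$status),
                  error = function(e) e)
  if (!inherits(adj, "error")) {
    put("measured_adjusted", "HR", cox_hr(adj))
    put("measured_adjusted", "RMST",
        standardized_rmst(adj, cbind(treatment = cohort$treatment,
                                     m_score = cohort$m_score), horizon))
  }
  put("measured_adjusted", "wHR",
      average_hazard_ratio(cohort, covariates = "m_score")$summary)
  extras$dr_ipsw_hr <- tryCatch(dr_ipsw_cox(cohort, "m_score")$summary,
                                error = function(e) conditionMessage(e))

  say("instrumental-variable analyses")
  iv <- tryCatch(two_sri_f(cohort), error = function(e) e)
  if (!inherits(iv, "error")) {
    extras$f_statistic <- iv$stage1$f_statistic
    extras$frailty_theta <- iv$stage2$theta
    put("omitted", "HR", iv$treatment_hr)
    put("omitted", "wHR", {
      x2 <- cbind(m_score = cohort$m_score,
                  residuals = iv$stage1$residuals)
      average_hazard_ratio(cohort, covariates = x2)$summary
    })
    put("omitted", "RMST", {
      cv <- iv_adjusted_curves(iv, cohort)
      extras$iv_curves <- cv
      effect_summary("RMST", cv$rmst_difference, NA_real_, NA_real_,
                     units = "months")
    })
  } else {
    put("omitted", "HR", stop(conditionMessage(iv)))
  }

  say("randomized-trial emulation")
  rct <- tryCatch(rerandomize_rct(cohort, 0.5,
                                  seed = derive_seed(seed, 14L)),
                  error = function(e) e)
  if (!inherits(rct, "error")) {
    put("rct", "ID", incidence_difference(rct, horizon))
    put("rct", "HR", cox_hr(fit_cox(cbind(treatment = rct$treatment),
                                    rct$observed_time, rct$status)))
    put("rct", "wHR", average_hazard_ratio(rct)$summary)
    put("rct", "RMST", rmst_difference(rct, horizon))
    put("rct", "mHR", estimate_marginal_psi(rct, weighting = "trivial",
                                            n_boot = n_boot,
                                            seed = derive_seed(seed, 15L))$hr)
    extras$rct_arm_sizes <- c(treated = sum(rct$treatment),
                              control = sum(1 - rct$treatment))
  }

  say("oracle analyses")
  orc <- tryCatch(oracle_analyses(cohort), error = function(e) e)
  if (!inherits(orc, "error")) {
    put("oracle", "HR", orc$cox_hr)
    put("oracle", "wHR", orc$whr)
    put("oracle", "RMST", orc$rmst)
    extras$counterfactual_curves <- orc$counterfactual_curves
  }

  structure(list(cells = cells, extras = extras,
                 meta = list(config = config, seed = seed,
                             horizon = horizon, n_boot = n_boot,
                             note = paste("`oracle` column is an extension",
                                          "beyond the usual five scenarios"))),
            class = "analysis_grid")
}

#' @export
print.analysis_grid <- function(x, digits = 2, ...) {
  measures <- names(x$cells[[1]])
  tab <- sapply(names(x$cells), function(sc) {
    vapply(measures, function(me) {
      cell <- x$cells[[sc]][[me]]
      if (is.null(cell)) return("")
      if (inherits(cell, "analysis_error")) return("<error>")
      format(cell, digits = digits)
    }, character(1))
  })
  rownames(tab) <- measures
  cat("Analysis grid (", x$meta$note, ")\n", sep = "")
  print(tab, quote = FALSE)
  invisible(x)
}

#' Serialize an analysis grid
#'
#' `grid_as_data_frame` flattens the grid to one row per non-empty cell;
#' `write_grid` writes CSV and/or JSON renditions.
#'
#' @param grid An `analysis_grid`.
#' @return A data frame with scenario, measure, estimate, CI, units.
#' @export
grid_as_data_frame <- function(grid) {
  rows <- list()
  for (sc in names(grid$cells)) {
    for (me in names(grid$cells[[sc]])) {
      cell <- grid$cells[[sc]][[me]]
      if (is.null(cell)) next
      if (inherits(cell, "analysis_error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc, measure = me, estimate = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, units = NA_character_,
          error = unclass(cell))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc, measure = me, estimate = cell$estimate,
          ci_low = cell$ci_low, ci_high = cell$ci_high,
          units = cell$units, error = NA_character_)
      }
    }
  }
  do.call(rbind, rows)
}

#' @rdname grid_as_data_frame
#' @param csv,json Optional output paths.
#' @export
write_grid <- function(grid, csv = NULL, json = NULL) {
  df <- grid_as_data_frame(grid)
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(list(note = grid$meta$note, results = df),
                         json, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(df)
}

#' Figure analogues of the published displays
#'
#' Writes simple base-graphics renditions: arm-specific KM curves, kernel
#' hazard curves, IV-adjusted curves, counterfactual curves, and the RCT
#' curves, one PNG per display.
#'
#' @param grid An `analysis_grid` (the extras carry the curves).
#' @param cohort The cohort analysed.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_figures <- function(grid, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  km_png <- file.path(dir, "km_by_arm.png")
  grDevices::png(km_png, width = 800, height = 600)
  i1 <- cohort$treatment == 1
  km1 <- kaplan_meier(cohort$observed_time[i1], cohort$status[i1])
  km0 <- kaplan_meier(cohort$observed_time[!i1], cohort$status[!i1])
  plot(stats::stepfun(km1$jump_times, c(0, 1 - km1$values)),
       do.points = FALSE, col = "firebrick", ylim = c(0, 0.12),
       main = "Cumulative incidence by arm", xlab = "months",
       ylab = "P(event)")
  graphics::lines(stats::stepfun(km0$jump_times, c(0, 1 - km0$values)),
                  do.points = FALSE, col = "navy")
  graphics::legend("topleft", c("TF-CAS", "TCAR"),
                   col = c("firebrick", "navy"), lty = 1)
  grDevices::dev.off()
  paths <- c(paths, km_png)

  hz_png <- file.path(dir, "hazard_by_arm.png")
  grDevices::png(hz_png, width = 800, height = 600)
  h1 <- kernel_hazard(cohort$observed_time[i1], cohort$status[i1])
  h0 <- kernel_hazard(cohort$observed_time[!i1], cohort$status[!i1])
  plot(h1$grid, h1$hazard, type = "l", col = "firebrick",
       main = "Kernel hazard estimates", xlab = "months",
       ylab = "events / month",
       ylim = c(0, max(h1$hazard, h0$hazard)))
  graphics::lines(h0$grid, h0$hazard, col = "navy")
  grDevices::dev.off()
  paths <- c(paths, hz_png)

  if (!is.null(grid$extras$counterfactual_curves)) {
    cf_png <- file.path(dir, "counterfactual_curves.png")
    grDevices::png(cf_png, width = 800, height = 600)
    cf <- grid$extras$counterfactual_curves
    plot(stats::stepfun(cf$all_treated$jump_times,
                        c(0, 1 - cf$all_treated$values)),
         do.points = FALSE, col = "firebrick", ylim = c(0, 0.12),
         main = "Counterfactual populations", xlab = "months",
         ylab = "P(event)")
    graphics::lines(stats::stepfun(cf$all_control$jump_times,
                                   c(0, 1 - cf$all_control$values)),
                    do.points = FALSE, col = "navy")
    grDevices::dev.off()
    paths <- c(paths, cf_png)
  }
  invisible(paths)
}
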