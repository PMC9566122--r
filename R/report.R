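#' Machine-readable fit reports
#'
#' `as_report()` flattens a fitted object into a plain list of scalars and
#' short vectors; `write_report()` serializes it as JSON.  Methods exist
#' for Cox fits (coefficients, hazard ratios with CIs, log-likelihood,
#' convergence, sample and event counts), gamma-frailty fits (plus the
#' frailty variance), 2SRI-F results (stage-1 coefficients, instrument F,
#' stage-2 summary, warnings) and marginal structural fits (psi, HR, CI,
#' bootstrap size, weighting, diagnostics).
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A named list (`as_report`); the file path, invisibly
#'   (`write_report`).
#' @export
as_report <- function(x, ...) UseMethod("as_report")

#' @export
as_report.cox_fit <- function(x, ...) {
  se <- sqrt(diag(if (!is.null(x$robust_covariance)) x$robust_covariance
                  else x$covariance))
  z <- stats::qnorm(0.975)
  list(model = "cox",
       coefficients = as.list(x$coefficients),
       hazard_ratios = as.list(exp(x$coefficients)),
       ci_low = as.list(exp(x$coefficients - z * se)),
       ci_high = as.list(exp(x$coefficients + z * se)),
       robust = !is.null(x$robust_covariance),
       loglik = x$loglik, converged = x$converged,
       n = x$n, events = x$n_events)
}

#' @export
as_report.frailty_cox_fit <- function(x, ...) {
  out <- NextMethod()
  out$model <- "frailty_cox"
  out$theta <- x$theta
  out$marginal_loglik <- x$marginal_loglik
  out
}

#' @export
as_report.two_sri_f_result <- function(x, ...) {
  list(model = "two_sri_f",
       stage1_coefficients = as.list(x$stage1$coefficients),
       f_statistic = x$stage1$f_statistic,
       weak_instrument = x$weak_instrument,
       theta = x$stage2$theta,
       treatment_hr = x$treatment_hr$estimate,
       ci_low = x$treatment_hr$ci_low,
       ci_high = x$treatment_hr$ci_high,
       stage2 = as_report(x$stage2))
}

#' @export
as_report.marginal_fit <- function(x, ...) {
  list(model = "marginal_cox",
       psi = x$psi, hr = x$hr$estimate,
       ci_low = x$hr$ci_low, ci_high = x$hr$ci_high,
       n_boot = x$n_boot, weighting = x$weighting,
       log_cumhaz_difference_sd = x$diagnostics$sd_pointwise)
}

#' @rdname as_report
#' @param file Output path.
#' @export
write_report <- function(x, file) {
  jsonlite::write_json(as_report(x), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
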