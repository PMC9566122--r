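#' One cell of the analysis grid: an effect estimate with its 95% CI
#'
#' @param measure Label, one of `"ID"`, `"HR"`, `"wHR"`, `"RMST"`, `"mHR"`.
#' @param estimate Point estimate.
#' @param ci_low,ci_high Confidence bounds.
#' @param level Confidence level (default 0.95).
#' @param units Units of the estimate: `"percentage points"`, `"ratio"` or
#'   `"months"`.
#' @return An object of class `effect_summary`.
#' @export
effect_summary <- function(measure, estimate, ci_low, ci_high,
                           level = 0.95, units) {
  measure <- match.arg(measure, c("ID", "HR", "wHR", "RMST", "mHR"))
  units <- match.arg(units, c("percentage points", "ratio", "months"))
  if (is.finite(ci_low) && is.finite(ci_high) &&
      !(ci_low <= estimate + 1e-10 && estimate <= ci_high + 1e-10)) {
    stop("confidence interval must bracket the estimate", call. = FALSE)
  }
  structure(list(measure = measure, estimate = estimate, ci_low = ci_low,
                 ci_high = ci_high, level = level, units = units),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("%s: %.3f [%.3f to %.3f] (%s, %d%% CI)\n", x$measure,
              x$estimate, x$ci_low, x$ci_high, x$units,
              round(100 * x$level)))
  invisible(x)
}

#' @export
format.effect_summary <- function(x, digits = 2, ...) {
  sprintf("%.*f [%.*f to %.*f]", digits, x$estimate, digits, x$ci_low,
          digits, x$ci_high)
}
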