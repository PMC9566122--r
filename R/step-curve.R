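#' Right-continuous step curves
#'
#' A `step_curve` stores a survival or cumulative-hazard estimate as a
#' right-continuous step function: jump times, the value attained at each
#' jump, a pointwise variance, and the number at risk just before the jump.
#' Survival curves implicitly start at 1 before the first jump; cumulative
#' hazards start at 0.
#'
#' @param jump_times Ascending positive event times (months).
#' @param values Curve value attained at each jump.
#' @param pointwise_variance Nonnegative pointwise variance at each jump.
#' @param n_at_risk Number (or weighted number) at risk just before each jump.
#' @param type `"survival"` or `"cumhaz"`.
#' @return An object of class `step_curve`.
#' @export
step_curve <- function(jump_times, values, pointwise_variance = NULL,
                       n_at_risk = NULL, type = c("survival", "cumhaz")) {
  type <- match.arg(type)
  jump_times <- as.numeric(jump_times)
  values <- as.numeric(values)
  if (is.null(pointwise_variance)) pointwise_variance <- rep(0, length(values))
  if (is.null(n_at_risk)) n_at_risk <- rep(NA_real_, length(values))
  if (length(jump_times) != length(values) ||
      length(values) != length(pointwise_variance) ||
      length(values) != length(n_at_risk)) {
    stop("step_curve components must have equal length", call. = FALSE)
  }
  if (is.unsorted(jump_times, strictly = FALSE)) {
    stop("jump_times must be ascending", call. = FALSE)
  }
  if (any(jump_times < 0)) stop("jump_times must be nonnegative", call. = FALSE)
  if (any(pointwise_variance < -1e-12, na.rm = TRUE)) {
    stop("pointwise_variance must be nonnegative", call. = FALSE)
  }
  if (type == "survival") {
    if (length(values) && (any(values < -1e-12) || any(values > 1 + 1e-12))) {
      stop("survival values must lie in [0, 1]", call. = FALSE)
    }
    if (length(values) > 1L && any(diff(values) > 1e-12)) {
      stop("survival curve must be nonincreasing", call. = FALSE)
    }
  } else {
    if (length(values) > 1L && any(diff(values) < -1e-12)) {
      stop("cumulative hazard must be nondecreasing", call. = FALSE)
    }
  }
  structure(
    list(jump_times = jump_times, values = values,
         pointwise_variance = pmax(pointwise_variance, 0),
         n_at_risk = n_at_risk, type = type),
    class = "step_curve"
  )
}

#' Evaluate a step curve at arbitrary times
#'
#' @param curve A [step_curve()].
#' @param times Times at which to evaluate (right-continuous convention).
#' @return Numeric vector of curve values.
#' @export
curve_eval <- function(curve, times) {
  stopifnot(inherits(curve, "step_curve"))
  start <- if (curve$type == "survival") 1 else 0
  idx <- findInterval(times, curve$jump_times)
  out <- c(start, curve$values)[idx + 1L]
  out
}

#' Integrate a survival step curve over [0, tau]
#'
#' Exact rectangle integral of the right-continuous step function.
#'
#' @param curve A survival [step_curve()].
#' @param tau Upper integration limit (months).
#' @return The integral, in months.
#' @export
curve_integral <- function(curve, tau) {
  stopifnot(inherits(curve, "step_curve"), curve$type == "survival")
  if (tau < 0) stop("tau must be nonnegative", call. = FALSE)
  tt <- curve$jump_times[curve$jump_times < tau]
  vv <- curve$values[curve$jump_times < tau]
  knots <- c(0, tt, tau)
  heights <- c(1, vv)
  sum(heights * diff(knots))
}

#' @export
print.step_curve <- function(x, ...) {
  cat(sprintf("<step_curve:%s> %d jumps on [%.3g, %.3g]\n", x$type,
              length(x$jump_times),
              if (length(x$jump_times)) min(x$jump_times) else NA,
              if (length(x$jump_times)) max(x$jump_times) else NA))
  invisible(x)
}

#' Export a step curve as a data frame / CSV
#'
#' Columns: time, estimate, var, ci_low, ci_high, n_risk.  Confidence
#' intervals use the log-log transform for survival curves and the plain
#' normal interval for cumulative hazards.
#'
#' @param curve A [step_curve()].
#' @param file Optional path; when given the table is written as CSV.
#' @param level Confidence level.
#' @return The data frame, invisibly when `file` is given.
#' @export
curve_as_table <- function(curve, file = NULL, level = 0.95) {
  stopifnot(inherits(curve, "step_curve"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  s <- curve$values
  v <- curve$pointwise_variance
  if (curve$type == "survival") {
    ci <- loglog_ci(s, v, z)
    lo <- ci$low; hi <- ci$high
  } else {
    se <- sqrt(v)
    lo <- pmax(s - z * se, 0)
    hi <- s + z * se
  }
  out <- data.frame(time = curve$jump_times, estimate = s, var = v,
                    ci_low = lo, ci_high = hi, n_risk = curve$n_at_risk)
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}

# log-log (complementary log-log) confidence bands for a survival estimate.
loglog_ci <- function(s, v, z) {
  low <- high <- rep(NA_real_, length(s))
  ok <- s > 0 & s < 1
  if (any(ok)) {
    # var of log(-log S) by delta method
    sig <- sqrt(v[ok]) / abs(s[ok] * log(s[ok]))
    theta <- log(-log(s[ok]))
    low[ok] <- exp(-exp(theta + z * sig))
    high[ok] <- exp(-exp(theta - z * sig))
  }
  low[s == 1] <- 1; high[s == 1] <- 1
  low[s == 0] <- 0; high[s == 0] <- 0
  list(low = low, high = high)
}
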