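#' Weighted Kaplan-Meier estimator
#'
#' Product-limit estimate of the survival function with Greenwood pointwise
#' variance.  Case weights generalize the estimator to inverse-probability
#' weighted samples; with equal weights it reduces to the classical KM.
#'
#' @param times Positive observed times (months).
#' @param status Event indicator (1 = event).
#' @param weights Optional nonnegative case weights.
#' @return A survival [step_curve()] with one jump per distinct event time.
#' @export
kaplan_meier <- function(times, status, weights = NULL) {
  km_na_core(times, status, weights, what = "km")
}

#' Nelson-Aalen cumulative hazard estimator
#'
#' @inheritParams kaplan_meier
#' @return A cumulative-hazard [step_curve()].
#' @export
nelson_aalen <- function(times, status, weights = NULL) {
  km_na_core(times, status, weights, what = "na")
}

km_na_core <- function(times, status, weights, what) {
  times <- as.numeric(times); status <- as.numeric(status)
  n <- length(times)
  if (length(status) != n) stop("length mismatch", call. = FALSE)
  if (any(times < 0)) stop("negative times", call. = FALSE)
  if (!all(status %in% c(0, 1))) stop("status must be 0/1", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) stop("negative weights", call. = FALSE)
  if (n == 0L) return(step_curve(numeric(0), numeric(0),
                                 type = if (what == "km") "survival" else "cumhaz"))
  ord <- order(times)
  t_s <- times[ord]; d_s <- status[ord]; w_s <- weights[ord]
  new_block <- c(TRUE, diff(t_s) > 0)
  block_id <- cumsum(new_block)
  atrisk <- revcumsum(w_s)[which(new_block)]       # weighted risk set per time
  dw <- as.numeric(rowsum(w_s * d_s, block_id))    # weighted events per time
  has_ev <- dw > 0
  tt <- t_s[which(new_block)][has_ev]
  Y <- atrisk[has_ev]; dk <- dw[has_ev]
  if (what == "km") {
    S <- cumprod(1 - dk / Y)
    gw_terms <- ifelse(Y > dk, dk / (Y * (Y - dk)), 0)
    v <- S^2 * cumsum(gw_terms)
    step_curve(tt, pmin(pmax(S, 0), 1), v, Y, type = "survival")
  } else {
    H <- cumsum(dk / Y)
    v <- cumsum(dk / Y^2)
    step_curve(tt, H, v, Y, type = "cumhaz")
  }
}

# Extract the survival columns of a cohort-like object.
cohort_columns <- function(cohort, cols = c("observed_time", "status",
                                            "treatment")) {
  df <- as.data.frame(cohort)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("cohort is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Incidence (cumulative event percentage) difference at a horizon
#'
#' Difference of the Kaplan-Meier event percentages, treated (TF-CAS) minus
#' control (TCAR), in percentage points, with a delta-method CI built from
#' the Greenwood variances.
#'
#' @param cohort A cohort (or data frame with `observed_time`, `status`,
#'   `treatment`).
#' @param horizon Months after the procedure (default 12).
#' @param weights Optional case weights.
#' @param level Confidence level.
#' @return An [effect_summary()] in percentage points.
#' @export
incidence_difference <- function(cohort, horizon = 12, weights = NULL,
                                 level = 0.95) {
  df <- cohort_columns(cohort)
  if (horizon > max(df$observed_time)) {
    stop(sprintf("horizon %.3g is beyond the last observed time %.3g",
                 horizon, max(df$observed_time)), call. = FALSE)
  }
  i1 <- df$treatment == 1
  w <- if (is.null(weights)) rep(1, nrow(df)) else weights
  km1 <- kaplan_meier(df$observed_time[i1], df$status[i1], w[i1])
  km0 <- kaplan_meier(df$observed_time[!i1], df$status[!i1], w[!i1])
  s1 <- curve_eval(km1, horizon); s0 <- curve_eval(km0, horizon)
  v1 <- curve_var_at(km1, horizon); v0 <- curve_var_at(km0, horizon)
  est <- 100 * (s0 - s1)
  se <- 100 * sqrt(v1 + v0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  effect_summary("ID", est, est - z * se, est + z * se, level,
                 units = "percentage points")
}

curve_var_at <- function(curve, t) {
  idx <- findInterval(t, curve$jump_times)
  c(0, curve$pointwise_variance)[idx + 1L]
}

#' Restricted mean survival time difference
#'
#' RMST difference at horizon `tau`, treated (TF-CAS) minus control (TCAR),
#' in months: the exact integral of each arm's Kaplan-Meier step curve over
#' `[0, tau]`.  A negative value means event-free time lost in the treated
#' arm.  The variance uses the standard restricted-mean influence formula
#' (sum over event times of the squared remaining area times the Greenwood
#' increment).
#'
#' @inheritParams incidence_difference
#' @param tau Horizon in months; must not exceed the largest observed time in
#'   either arm.
#' @return An [effect_summary()] in months.
#' @export
rmst_difference <- function(cohort, tau = 12, weights = NULL, level = 0.95) {
  df <- cohort_columns(cohort)
  i1 <- df$treatment == 1
  max_ok <- min(max(df$observed_time[i1]), max(df$observed_time[!i1]))
  if (tau > max_ok) {
    stop(sprintf("tau %.4g exceeds the achievable maximum %.4g", tau, max_ok),
         call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, nrow(df)) else weights
  a1 <- rmst_arm(df$observed_time[i1], df$status[i1], w[i1], tau)
  a0 <- rmst_arm(df$observed_time[!i1], df$status[!i1], w[!i1], tau)
  est <- a1$rmst - a0$rmst
  se <- sqrt(a1$var + a0$var)
  z <- stats::qnorm(1 - (1 - level) / 2)
  effect_summary("RMST", est, est - z * se, est + z * se, level,
                 units = "months")
}

rmst_arm <- function(times, status, weights, tau) {
  km <- kaplan_meier(times, status, weights)
  rmst <- curve_integral(km, tau)
  keep <- km$jump_times <= tau & km$n_at_risk > 0
  tt <- km$jump_times[keep]
  # integral from t0 to tau of S(u)du:
  area_after <- vapply(tt, function(t0) {
    knots <- c(t0, km$jump_times[km$jump_times > t0 & km$jump_times < tau], tau)
    heights <- curve_eval(km, knots[-length(knots)])
    sum(heights * diff(knots))
  }, numeric(1))
  # Greenwood-style increments d/(Y(Y-d)) at each event time <= tau
  Y <- km$n_at_risk[keep]
  S_prev <- c(1, km$values)[which(keep)]
  S_now <- km$values[keep]
  dk <- Y * (1 - S_now / S_prev)
  incr <- ifelse(Y > dk, dk / (Y * (Y - dk)), 0)
  list(rmst = rmst, var = sum(area_after^2 * incr))
}

#' Kernel-smoothed hazard function
#'
#' Epanechnikov smoothing of the Nelson-Aalen increments with reflection
#' boundary correction at 0 and at the follow-up end.
#'
#' @inheritParams kaplan_meier
#' @param bandwidth Kernel bandwidth in months (default 1.5).
#' @param grid Evaluation grid (default 121 points on `[0, tmax]`).
#' @param tmax Right boundary for reflection (default largest observed time).
#' @return A `hazard_curve`: list with `grid`, `hazard` (events per month)
#'   and `bandwidth`.
#' @export
kernel_hazard <- function(times, status, bandwidth = 1.5, grid = NULL,
                          tmax = NULL) {
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  if (is.null(tmax)) tmax <- max(times)
  if (is.null(grid)) grid <- seq(0, tmax, length.out = 121L)
  if (length(grid) == 0L) stop("empty grid", call. = FALSE)
  na <- nelson_aalen(times, status)
  tt <- na$jump_times
  dH <- diff(c(0, na$values))
  epan <- function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0)
  haz <- vapply(grid, function(g) {
    if (!length(tt)) return(0)
    k <- epan((g - tt) / bandwidth) +
      epan((g + tt) / bandwidth) +                 # reflection at 0
      epan((2 * tmax - g - tt) / bandwidth)        # reflection at tmax
    sum(k * dH) / bandwidth
  }, numeric(1))
  structure(list(grid = grid, hazard = pmax(haz, 0), bandwidth = bandwidth),
            class = "hazard_curve")
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat(sprintf("<hazard_curve> %d grid points, bandwidth %.2f months\n",
              length(x$grid), x$bandwidth))
  invisible(x)
}
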