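#' Propensity-score model and inverse-propensity weights
#'
#' Logistic regression (iteratively reweighted least squares via
#' `stats::glm`) of treatment on measured covariates only.  The returned
#' weights are `1/p` for treated and `1/(1-p)` for control subjects;
#' stabilized weights multiply by the marginal arm probabilities.
#'
#' @param cohort A cohort or data frame.
#' @param covariates Character vector of measured covariate columns
#'   (`u_score` is rejected by contract: the propensity model may only see
#'   measured information).
#' @param stabilized Use stabilized weights.
#' @return A `propensity_result`: `scores`, `coefficients`, `weights`,
#'   `stabilized`.
#' @export
fit_propensity <- function(cohort, covariates = "m_score",
                           stabilized = FALSE) {
  df <- cohort_columns(cohort, c("treatment", covariates))
  if ("u_score" %in% covariates) {
    stop("u_score is unmeasured and may not enter the propensity model",
         call. = FALSE)
  }
  form <- stats::as.formula(paste("treatment ~",
                                  paste(covariates, collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = df)
  p <- stats::fitted(fit)
  if (any(p <= 1e-12) || any(p >= 1 - 1e-12) || any(abs(stats::coef(fit)) > 15)) {
    big <- names(which.max(abs(stats::coef(fit))[-1]))
    stop(sprintf("perfect (or near-perfect) separation in the propensity model (covariate: %s)",
                 big), call. = FALSE)
  }
  w <- ifelse(df$treatment == 1, 1 / p, 1 / (1 - p))
  if (stabilized) {
    pt <- mean(df$treatment)
    w <- w * ifelse(df$treatment == 1, pt, 1 - pt)
  }
  structure(list(scores = p, coefficients = stats::coef(fit), weights = w,
                 stabilized = stabilized, treatment = df$treatment),
            class = "propensity_result")
}

#' @export
print.propensity_result <- function(x, ...) {
  cat(sprintf("<propensity_result> n = %d, %sweights in [%.3g, %.3g]\n",
              length(x$scores), if (x$stabilized) "stabilized " else "",
              min(x$weights), max(x$weights)))
  invisible(x)
}

#' Weighted standardized mean difference of a covariate between arms
#'
#' Balance diagnostic: difference of weighted means divided by the pooled
#' unweighted standard deviation.
#'
#' @param x Covariate values.
#' @param treatment 0/1 arm labels.
#' @param weights Case weights (default 1).
#' @return The standardized mean difference.
#' @export
standardized_mean_difference <- function(x, treatment, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(x))
  i1 <- treatment == 1
  m1 <- stats::weighted.mean(x[i1], weights[i1])
  m0 <- stats::weighted.mean(x[!i1], weights[!i1])
  s <- sqrt((stats::var(x[i1]) + stats::var(x[!i1])) / 2)
  (m1 - m0) / s
}

#' Greedy nearest-neighbour propensity matching
#'
#' 1:1 matching without replacement on the logit of the propensity score,
#' treated subjects processed in seeded random order, with a caliper
#' expressed in standard deviations of the logit score.
#'
#' @param propensity A [fit_propensity()] result.
#' @param caliper Caliper width in SD-of-logit units (default 0.2).
#' @param seed Seed for the processing order.
#' @return A `matched_sample`: data frame `pairs` (`treated_id`,
#'   `control_id`, `distance`, row indices into the cohort) plus the
#'   caliper used.
#' @export
match_nearest <- function(propensity, caliper = 0.2, seed = 1L) {
  if (caliper <= 0) stop("caliper must be positive", call. = FALSE)
  lp <- logit(propensity$scores)
  trt <- propensity$treatment
  idx_t <- which(trt == 1); idx_c <- which(trt == 0)
  if (!length(idx_t) || !length(idx_c)) {
    stop("both arms must be non-empty for matching", call. = FALSE)
  }
  cal <- caliper * stats::sd(lp)
  ord_t <- with_seed(seed, sample(idx_t))
  # controls kept sorted; removal uses skip pointers with path compression
  oc <- idx_c[order(lp[idx_c])]
  nc <- length(oc)
  lp_c <- lp[oc]
  removed <- logical(nc)
  nxt <- c(seq_len(nc)[-1L], NA_integer_)
  prv <- c(NA_integer_, seq_len(nc - 1L))
  n_live <- nc
  live_before <- function(i) {         # nearest live index <= i (chasing prv)
    start <- i
    while (!is.na(i) && removed[i]) i <- prv[i]
    if (!is.na(start) && removed[start]) prv[start] <<- i
    i
  }
  live_after <- function(i) {
    start <- i
    while (!is.na(i) && removed[i]) i <- nxt[i]
    if (!is.na(start) && removed[start]) nxt[start] <<- i
    i
  }
  pairs_t <- pairs_c <- integer(0)
  dist <- numeric(0)
  for (ti in ord_t) {
    if (n_live == 0L) break
    target <- lp[ti]
    pos <- findInterval(target, lp_c)
    left <- if (pos >= 1L) live_before(pos) else NA_integer_
    right <- if (pos < nc) live_after(pos + 1L) else NA_integer_
    best <- NA_integer_; bestd <- Inf
    if (!is.na(left) && abs(target - lp_c[left]) < bestd) {
      bestd <- abs(target - lp_c[left]); best <- left
    }
    if (!is.na(right) && abs(target - lp_c[right]) < bestd) {
      bestd <- abs(target - lp_c[right]); best <- right
    }
    if (!is.na(best) && bestd <= cal) {
      pairs_t <- c(pairs_t, ti); pairs_c <- c(pairs_c, oc[best])
      dist <- c(dist, bestd)
      pb <- prv[best]; nb <- nxt[best]
      if (!is.na(pb)) nxt[pb] <- nb
      if (!is.na(nb)) prv[nb] <- pb
      removed[best] <- TRUE
      n_live <- n_live - 1L
    }
  }
  pairs <- data.frame(treated_id = pairs_t, control_id = pairs_c,
                      distance = dist)
  structure(list(pairs = pairs, caliper = caliper, caliper_abs = cal),
            class = "matched_sample")
}

#' @export
print.matched_sample <- function(x, ...) {
  cat(sprintf("<matched_sample> %d pairs, caliper %.2f SD (%.4f logit units)\n",
              nrow(x$pairs), x$caliper, x$caliper_abs))
  invisible(x)
}

#' Subset a cohort to a matched sample
#'
#' @param cohort The cohort the match was computed on.
#' @param matched A [match_nearest()] result.
#' @return A `tcar_cohort` restricted to matched subjects.
#' @export
matched_cohort <- function(cohort, matched) {
  keep <- c(matched$pairs$treated_id, matched$pairs$control_id)
  df <- as.data.frame(cohort)[keep, , drop = FALSE]
  new_cohort(df, attr(cohort, "config"), attr(cohort, "provenance"))
}

#' Export matched pairs as CSV
#'
#' @param matched A [match_nearest()] result.
#' @param file Path.
#' @export
write_pairs_csv <- function(matched, file) {
  utils::write.csv(matched$pairs, file, row.names = FALSE)
  invisible(file)
}

#' Doubly-robust IPSW Cox model
#'
#' Inverse-propensity weighted Cox regression that also includes the
#' propensity covariates in the outcome model; consistent if either the
#' propensity model or the outcome model is correct.  CI from the robust
#' sandwich covariance.
#'
#' @inheritParams fit_propensity
#' @param level Confidence level.
#' @return A list with `summary` (treatment HR as [effect_summary()]),
#'   `fit`, and `propensity`.
#' @export
dr_ipsw_cox <- function(cohort, covariates = "m_score", level = 0.95) {
  df <- cohort_columns(cohort, c("observed_time", "status", "treatment",
                                 covariates))
  ps <- fit_propensity(df, covariates)
  X <- cbind(treatment = df$treatment, as.matrix(df[covariates]))
  fit <- fit_cox(X, df$observed_time, df$status, weights = ps$weights)
  list(summary = cox_hr(fit, "treatment", level = level), fit = fit,
       propensity = ps)
}
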