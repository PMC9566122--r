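#' Gamma-frailty Cox regression by EM
#'
#' Fits a proportional-hazards model with a multiplicative gamma frailty
#' (mean 1, variance `theta`), by default one frailty per subject.  For a
#' fixed `theta` the EM exploits gamma conjugacy: the E-step posterior
#' frailty for group i is `(1/theta + d_i) / (1/theta + Lambda_i)` where
#' `d_i` counts the group's events and `Lambda_i` its accumulated hazard;
#' the M-step is a Cox fit with `log` posterior frailties as offset.
#' `theta` itself is profiled by golden-section search on the marginal
#' log-likelihood over `[0, theta_max]`.
#'
#' @inheritParams fit_cox
#' @param groups Frailty sharing: one label per subject (default: each
#'   subject its own frailty).
#' @param theta Fix the frailty variance instead of estimating it;
#'   `theta = 0` reproduces [fit_cox()] exactly.
#' @param theta_max Upper bound of the profile search (default 10).
#' @param em_tol,em_max_iter EM convergence controls.
#' @param profile_tol Golden-section bracket tolerance on theta.
#' @return A `frailty_cox_fit`, extending `cox_fit` with `theta`,
#'   `posterior_frailties`, and `marginal_loglik`.
#' @export
fit_frailty_cox <- function(covariates, times, status, groups = NULL,
                            ties = c("efron", "breslow"), theta = NULL,
                            theta_max = 10, em_tol = 1e-6,
                            em_max_iter = 200L, profile_tol = 1e-4) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (sum(status) == 0) stop("no events in the data", call. = FALSE)
  if (is.null(groups)) groups <- seq_len(n)
  gid <- match(groups, unique(groups))

  warm <- new.env(parent = emptyenv())
  warm$beta <- NULL; warm$omega <- NULL
  fit_at <- function(th) {
    res <- frailty_em(X, times, status, gid, th, ties, em_tol, em_max_iter,
                      init_beta = warm$beta, init_omega = warm$omega)
    warm$beta <- res$fit$coefficients
    warm$omega <- res$frailty
    res
  }

  if (!is.null(theta)) {
    res <- fit_at(theta)
    theta_hat <- theta
  } else {
    # golden-section maximization of the profile marginal log-likelihood
    gr <- (sqrt(5) - 1) / 2
    a <- 0; b <- theta_max
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- fit_at(x1)$marginal_loglik; f2 <- fit_at(x2)$marginal_loglik
    while (b - a > profile_tol) {
      if (f1 >= f2) {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- fit_at(x1)$marginal_loglik
      } else {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- fit_at(x2)$marginal_loglik
      }
    }
    theta_hat <- (a + b) / 2
    res <- fit_at(theta_hat)
    if (theta_hat > theta_max - 10 * profile_tol) {
      warning("frailty variance estimate hit the search upper bound",
              call. = FALSE)
    }
  }

  fit <- res$fit
  out <- unclass(fit)
  out$theta <- theta_hat
  out$posterior_frailties <- res$frailty[gid]
  out$marginal_loglik <- res$marginal_loglik
  out$em_iterations <- res$em_iterations
  out$converged <- fit$converged && res$em_converged
  class(out) <- c("frailty_cox_fit", "cox_fit")
  out
}

# EM at fixed theta.  Returns the converged inner Cox fit (with offset),
# posterior frailties per group, and the gamma marginal log-likelihood.
frailty_em <- function(X, times, status, gid, theta, ties, em_tol,
                       em_max_iter, init_beta = NULL, init_omega = NULL) {
  n <- nrow(X)
  n_g <- max(gid)
  omega <- if (is.null(init_omega) || theta <= 0) rep(1, n_g) else init_omega
  beta <- init_beta
  fit <- NULL
  em_converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # inner fits stay quiet; convergence status is carried on the result
    fit <- suppressWarnings(
      fit_cox(X, times, status, offset = log(omega)[gid], ties = ties,
              robust = FALSE, init = beta))
    if (theta <= 0) { em_converged <- TRUE; break }
    lam_i <- subject_cumhaz(fit, X, times)          # Lambda0(Y_i) e^{x_i beta}
    d_g <- as.numeric(rowsum(as.numeric(status), gid))
    lam_g <- as.numeric(rowsum(lam_i, gid))
    new_omega <- (1 / theta + d_g) / (1 / theta + lam_g)
    delta <- max(abs(new_omega - omega),
                 if (is.null(beta)) Inf else max(abs(fit$coefficients - beta)))
    omega <- new_omega
    beta <- fit$coefficients
    if (delta < em_tol) { em_converged <- TRUE; break }
    if (iter >= em_max_iter) break
  }
  ml <- frailty_marginal_loglik(fit, X, times, status, gid, theta)
  list(fit = fit, frailty = omega, marginal_loglik = ml,
       em_iterations = iter, em_converged = em_converged)
}

# Lambda0(Y_i) * exp(x_i beta), with the Breslow baseline of `fit`
# (frailty offsets excluded: the baseline absorbs covariates only).
subject_cumhaz <- function(fit, X, times) {
  base <- fit$baseline_cumhaz
  idx <- findInterval(times, base$jump_times)
  lam0 <- c(0, base$values)[idx + 1L]
  lam0 * exp(drop(X %*% fit$coefficients))
}

# Observed (gamma-integrated) log-likelihood given the EM-converged
# (beta, Lambda0) at this theta.  For group g with d_g events:
#   sum_events log dLambda0(Y_i) e^{x_i beta}
#   + d_g-dependent gamma terms - (1/theta + d_g) log(1 + theta Lambda_g).
frailty_marginal_loglik <- function(fit, X, times, status, gid, theta) {
  base <- fit$baseline_cumhaz
  dlam <- diff(c(0, base$values))
  idx <- match(times, base$jump_times)
  ev <- which(status == 1)
  eta <- drop(X %*% fit$coefficients)
  ll_events <- sum(log(dlam[idx[ev]]) + eta[ev])
  lam_g <- as.numeric(rowsum(subject_cumhaz(fit, X, times), gid))
  d_g <- as.numeric(rowsum(as.numeric(status), gid))
  if (theta <= 0) return(ll_events - sum(lam_g))
  inv <- 1 / theta
  gamma_terms <- lgamma(inv + d_g) - lgamma(inv) - d_g * log(inv)
  ll_events + sum(gamma_terms - (inv + d_g) * log1p(theta * lam_g))
}

#' @export
print.frailty_cox_fit <- function(x, ...) {
  cat(sprintf("Gamma-frailty Cox fit: theta = %.4f, marginal loglik = %.3f\n",
              x$theta, x$marginal_loglik))
  NextMethod()
}
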