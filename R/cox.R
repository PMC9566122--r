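#' Cox proportional-hazards regression by Newton-Raphson
#'
#' Maximizes the (optionally case-weighted) Cox partial likelihood for
#' right-censored data.  Supports Efron and Breslow handling of tied event
#' times, an offset, and per-event-time weights (used by the average hazard
#' ratio estimator).  A robust (Lin-Wei sandwich) covariance is computed
#' whenever case weights or time weights are present, and on request.
#'
#' @param covariates Numeric matrix (n x p), one column per covariate; column
#'   names are kept as coefficient names.  Constant columns are rejected.
#' @param times Positive observed times.
#' @param status Event indicator (1 = event, 0 = censored).
#' @param weights Optional nonnegative case weights (default 1).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param offset Optional linear-predictor offset.
#' @param robust Force computation of the robust covariance.
#' @param time_weights Optional [weight_function_spec()] giving a weight for
#'   each distinct event time (ascending order); the score contribution of
#'   each event time is multiplied by its weight.
#' @param init Starting coefficients (default 0).
#' @param max_iter,tol Newton-Raphson controls; convergence requires the
#'   gradient max-norm below `tol`.
#' @return A `cox_fit` object: `coefficients` (log hazard ratios),
#'   `covariance` (model-based), `robust_covariance` (or `NULL`),
#'   `baseline_cumhaz` (Breslow estimate at covariates 0 as a
#'   [step_curve()]), `loglik`, `loglik_null`, `iterations`, `converged`,
#'   `n`, `n_events`.
#' @export
fit_cox <- function(covariates, times, status, weights = NULL,
                    ties = c("efron", "breslow"), offset = NULL,
                    robust = NULL, time_weights = NULL, init = NULL,
                    max_iter = 30L, tol = 1e-9) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  times <- as.numeric(times)
  status <- as.numeric(status)
  if (length(times) != n || length(status) != n) {
    stop("covariates, times and status must have matching lengths",
         call. = FALSE)
  }
  if (any(times < 0)) stop("times must be nonnegative", call. = FALSE)
  if (!all(status %in% c(0, 1))) stop("status must be 0/1", call. = FALSE)
  if (is.null(weights)) {
    weights <- rep(1, n)
    has_w <- FALSE
  } else {
    weights <- as.numeric(weights)
    if (any(weights < 0) || any(!is.finite(weights))) {
      stop("weights must be finite and nonnegative", call. = FALSE)
    }
    has_w <- TRUE
  }
  if (is.null(offset)) offset <- rep(0, n)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant covariate column: %s",
                 paste(colnames(X)[sds == 0], collapse = ", ")),
         call. = FALSE)
  }
  if (sum(status) == 0) stop("no events in the data", call. = FALSE)

  eng <- cox_engine(X, times, status, weights, offset, ties,
                    time_weights = time_weights, init = init,
                    max_iter = max_iter, tol = tol)
  dimnames(eng$covariance) <- list(colnames(X), colnames(X))
  want_robust <- isTRUE(robust) ||
    (is.null(robust) && (has_w || !is.null(time_weights)))
  rob <- if (want_robust) cox_robust_cov(eng) else NULL
  if (!is.null(rob)) dimnames(rob) <- list(colnames(X), colnames(X))

  if (!eng$converged) {
    warning(sprintf(
      "Cox fit did not converge in %d iterations (gradient max %.3g)",
      eng$iterations, eng$grad_max), call. = FALSE)
  }
  if (any(abs(eng$beta) > 15)) {
    warning("very large coefficient: possible monotone likelihood / separation",
            call. = FALSE)
  }

  structure(list(
    coefficients = stats::setNames(eng$beta, colnames(X)),
    covariance = eng$covariance,
    robust_covariance = rob,
    baseline_cumhaz = eng$baseline_cumhaz,
    loglik = eng$loglik, loglik_null = eng$loglik_null,
    iterations = eng$iterations, converged = eng$converged,
    n = n, n_events = sum(status), ties = ties,
    engine = eng
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  se <- sqrt(diag(x$covariance))
  hr <- exp(x$coefficients)
  cat(sprintf("Cox fit (%s ties): n = %d, events = %d, loglik = %.3f%s\n",
              x$ties, x$n, x$n_events, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  tab <- data.frame(coef = x$coefficients, `exp(coef)` = hr, se = se,
                    z = x$coefficients / se, check.names = FALSE)
  print(round(tab, 4))
  invisible(x)
}

#' Hazard ratio summary for one coefficient of a Cox-type fit
#'
#' @param fit A `cox_fit` (or object with compatible fields).
#' @param term Coefficient name (default first).
#' @param level Confidence level.
#' @param robust Use the robust covariance when available (default: yes when
#'   present).
#' @param measure Label for the resulting [effect_summary()].
#' @return An [effect_summary()] on the hazard-ratio scale.
#' @export
cox_hr <- function(fit, term = 1L, level = 0.95, robust = NULL,
                   measure = "HR") {
  V <- fit$covariance
  if ((is.null(robust) || isTRUE(robust)) && !is.null(fit$robust_covariance)) {
    V <- fit$robust_covariance
  }
  b <- unname(fit$coefficients[term])
  se <- unname(sqrt(diag(V))[term])
  z <- stats::qnorm(1 - (1 - level) / 2)
  effect_summary(measure, exp(b), exp(b - z * se), exp(b + z * se),
                 level = level, units = "ratio")
}

# ---------------------------------------------------------------------------
# Engine internals

revcumsum <- function(v) rev(cumsum(rev(v)))

# Precompute the sorted layout shared by all Newton iterations.
cox_layout <- function(X, times, status, weights, offset) {
  ord <- order(times)
  X <- X[ord, , drop = FALSE]
  t_s <- times[ord]; d_s <- status[ord]
  w_s <- weights[ord]; off_s <- offset[ord]
  n <- length(t_s)
  new_block <- c(TRUE, diff(t_s) > 0)
  block_id <- cumsum(new_block)
  block_start <- which(new_block)            # first sorted index of each block
  first_idx <- block_start[block_id]         # risk-set start per subject
  ev_idx <- which(d_s == 1)
  ev_block <- block_id[ev_idx]
  ub <- sort(unique(ev_block))               # blocks containing >= 1 event
  # map: for each event block, its risk-set start and member event indices
  eb_first <- block_start[ub]
  eb_time <- t_s[eb_first]
  d_k <- tabulate(match(ev_block, ub))
  list(X = X, t = t_s, d = d_s, w = w_s, off = off_s, ord = ord, n = n,
       first_idx = first_idx, ev_idx = ev_idx, ev_block_pos = match(ev_block, ub),
       eb_first = eb_first, eb_time = eb_time, d_k = d_k, n_eb = length(ub))
}

cox_engine <- function(X, times, status, weights, offset,
                       ties = "efron", time_weights = NULL, init = NULL,
                       max_iter = 30L, tol = 1e-9) {
  p <- ncol(X)
  lay <- cox_layout(X, times, status, weights, offset)
  xbar <- colSums(lay$w * lay$X) / sum(lay$w)
  Xc <- sweep(lay$X, 2, xbar)
  q <- p * (p + 1L) / 2L
  pair_i <- pair_j <- integer(q)
  k <- 0L
  for (i in seq_len(p)) for (j in i:p) {
    k <- k + 1L; pair_i[k] <- i; pair_j[k] <- j
  }
  XX <- Xc[, pair_i, drop = FALSE] * Xc[, pair_j, drop = FALSE]

  wt_k <- resolve_time_weights(time_weights, lay)

  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
  dev_fun <- function(beta) cox_iter(beta, lay, Xc, XX, pair_i, pair_j,
                                     ties, wt_k)
  it <- dev_fun(beta)
  loglik_null <- if (all(beta == 0)) it$loglik else
    cox_iter(rep(0, p), lay, Xc, XX, pair_i, pair_j, ties, wt_k)$loglik
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- solve(it$hess, it$grad)
    new_beta <- beta + step
    new_it <- dev_fun(new_beta)
    halvings <- 0L
    while ((!is.finite(new_it$loglik) || new_it$loglik < it$loglik - 1e-12) &&
           halvings < 20L) {
      halvings <- halvings + 1L
      step <- step / 2
      new_beta <- beta + step
      new_it <- dev_fun(new_beta)
    }
    beta <- new_beta; it <- new_it
    # absolute gradient criterion, or a Newton step at numerical noise level
    if (max(abs(it$grad)) < tol || max(abs(step)) < 1e-11) {
      converged <- TRUE; break
    }
  }

  # Breslow baseline increments at covariates = 0 (uncentered scale)
  dlam_c <- it$Dw_k / it$S0_k
  dlam0 <- dlam_c * exp(-sum(xbar * beta))
  base <- step_curve(lay$eb_time, cumsum(dlam0), type = "cumhaz")

  list(beta = beta, covariance = solve(it$hess),
       loglik = it$loglik, loglik_null = loglik_null,
       iterations = iter, converged = converged, grad_max = max(abs(it$grad)),
       baseline_cumhaz = base, lay = lay, Xc = Xc, xbar = xbar,
       S0_k = it$S0_k, S1_k = it$S1_k, Dw_k = it$Dw_k, dlam_c = dlam_c,
       eta_c = it$eta_c, wt_k = wt_k, hess = it$hess)
}

resolve_time_weights <- function(time_weights, lay) {
  if (is.null(time_weights)) return(rep(1, lay$n_eb))
  if (inherits(time_weights, "weight_function_spec")) {
    wt <- weight_values(time_weights, lay$eb_time)
  } else {
    wt <- as.numeric(time_weights)
  }
  if (length(wt) != lay$n_eb) {
    stop(sprintf("time weights must have one value per distinct event time (%d)",
                 lay$n_eb), call. = FALSE)
  }
  if (any(wt < 0) || all(wt == 0)) {
    stop("time weights must be nonnegative and not all zero", call. = FALSE)
  }
  wt / mean(wt)
}

# One evaluation of weighted partial log-likelihood, gradient and (negative)
# Hessian at beta.  Centered covariates throughout.
cox_iter <- function(beta, lay, Xc, XX, pair_i, pair_j, ties, wt_k) {
  p <- ncol(Xc)
  eta <- drop(Xc %*% beta) + lay$off
  r <- lay$w * exp(eta)
  rc0 <- revcumsum(r)
  RC1 <- apply(r * Xc, 2, revcumsum)
  if (p == 1L) RC1 <- matrix(RC1, ncol = 1L)
  RC2 <- apply(r * XX, 2, revcumsum)
  if (ncol(XX) == 1L) RC2 <- matrix(RC2, ncol = 1L)

  fb <- lay$eb_first
  S0 <- rc0[fb]
  S1 <- RC1[fb, , drop = FALSE]
  S2 <- RC2[fb, , drop = FALSE]

  ev <- lay$ev_idx
  pos <- lay$ev_block_pos          # which event block each event belongs to
  w_ev <- lay$w[ev]
  Dw <- as.numeric(rowsum(w_ev, pos, reorder = TRUE))
  sum_wx <- rowsum(w_ev * Xc[ev, , drop = FALSE], pos, reorder = TRUE)

  d_k <- lay$d_k
  loglik <- sum(wt_k[pos] * w_ev * eta[ev])

  grad <- colSums(wt_k * sum_wx)
  hess <- matrix(0, p, p)
  upper <- cbind(pair_i, pair_j)

  single <- d_k == 1L | ties == "breslow"
  if (any(single)) {
    s0 <- S0[single]; dw <- Dw[single]; wt <- wt_k[single]
    loglik <- loglik - sum(wt * dw * log(s0))
    xb <- S1[single, , drop = FALSE] / s0
    grad <- grad - colSums(wt * dw * xb)
    vcontrib <- S2[single, , drop = FALSE] / s0 -
      xb[, pair_i, drop = FALSE] * xb[, pair_j, drop = FALSE]
    hvec <- colSums(wt * dw * vcontrib)
    H <- matrix(0, p, p); H[upper] <- hvec; H[upper[, 2:1, drop = FALSE]] <- hvec
    hess <- hess + H
  }
  multi <- which(!single)
  if (length(multi)) {
    # Efron correction for tied event times (weighted form, as in coxph)
    sum_rx_ev <- rowsum((r * Xc)[ev, , drop = FALSE], pos, reorder = TRUE)
    sum_rxx_ev <- rowsum((r * XX)[ev, , drop = FALSE], pos, reorder = TRUE)
    sum_r_ev <- as.numeric(rowsum(r[ev], pos, reorder = TRUE))
    for (b in multi) {
      d <- d_k[b]; meanwt <- Dw[b] / d; wt <- wt_k[b]
      for (l in 0:(d - 1L)) {
        frac <- l / d
        s0l <- S0[b] - frac * sum_r_ev[b]
        s1l <- S1[b, ] - frac * sum_rx_ev[b, ]
        s2l <- S2[b, ] - frac * sum_rxx_ev[b, ]
        loglik <- loglik - wt * meanwt * log(s0l)
        xb <- s1l / s0l
        grad <- grad - wt * meanwt * xb
        hvec <- wt * meanwt * (s2l / s0l - xb[pair_i] * xb[pair_j])
        H <- matrix(0, p, p); H[upper] <- hvec
        H[upper[, 2:1, drop = FALSE]] <- hvec
        hess <- hess + H
      }
    }
  }
  list(loglik = loglik, grad = grad, hess = hess,
       S0_k = S0, S1_k = S1, Dw_k = Dw, eta_c = eta)
}

# Lin-Wei sandwich covariance from Breslow-form score residuals.
cox_robust_cov <- function(eng) {
  lay <- eng$lay
  p <- ncol(eng$Xc)
  xbar_k <- eng$S1_k / eng$S0_k                  # risk-set means per event block
  dlam <- eng$wt_k * eng$dlam_c                  # time-weighted increments
  cum_dlam <- cumsum(dlam)
  cum_g <- apply(xbar_k * dlam, 2, cumsum)
  if (p == 1L) cum_g <- matrix(cum_g, ncol = 1L)
  idx <- findInterval(lay$t, lay$eb_time)        # blocks with t_b <= Y_i
  Lam_i <- c(0, cum_dlam)[idx + 1L]
  G_i <- rbind(0, cum_g)[idx + 1L, , drop = FALSE]
  exp_eta <- exp(eng$eta_c)
  # event-term: wt at the subject's own event time
  pos_of_subject <- rep(NA_integer_, lay$n)
  pos_of_subject[lay$ev_idx] <- lay$ev_block_pos
  U <- matrix(0, lay$n, p)
  ev <- lay$ev_idx
  U[ev, ] <- eng$wt_k[pos_of_subject[ev]] *
    (eng$Xc[ev, , drop = FALSE] - xbar_k[pos_of_subject[ev], , drop = FALSE])
  U <- U - exp_eta * (eng$Xc * Lam_i - G_i)
  WU <- lay$w * U
  meat <- crossprod(WU)
  A_inv <- solve(eng$hess)
  A_inv %*% meat %*% A_inv
}

#' Predicted survival curve from a Cox fit at fixed covariates
#'
#' @param fit A `cox_fit`.
#' @param newx Numeric vector of covariate values (uncentered scale).
#' @return A survival [step_curve()] on the event-time grid.
#' @export
cox_survival <- function(fit, newx) {
  base <- fit$baseline_cumhaz
  risk <- exp(sum(as.numeric(newx) * fit$coefficients))
  step_curve(base$jump_times, exp(-base$values * risk), type = "survival")
}
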