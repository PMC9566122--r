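# Shared fixtures, built in code.

# Two-arm exponential survival data with optional uniform censoring.
exp_two_arm <- function(n_per_arm, rate0, rate1, cens_max = Inf, seed = 1) {
  tcarsim:::with_seed(seed, {
    x <- rep(c(0L, 1L), each = n_per_arm)
    t0 <- stats::rexp(2 * n_per_arm, ifelse(x == 1, rate1, rate0))
    cens <- if (is.finite(cens_max)) stats::runif(2 * n_per_arm, 0, cens_max)
            else rep(Inf, 2 * n_per_arm)
    data.frame(treatment = x, observed_time = pmin(t0, cens),
               status = as.integer(t0 <= cens))
  })
}

# The default cohort is expensive enough to share across test files.
.cohort_cache <- new.env(parent = emptyenv())
default_cohort_cached <- function() {
  if (is.null(.cohort_cache$co)) .cohort_cache$co <- generate_cohort()
  .cohort_cache$co
}

# Independent partial log-likelihood by direct enumeration over risk sets
# (Breslow ties), for tiny fixtures.  Deliberately naive.
enum_partial_loglik <- function(beta, x, times, status) {
  eta <- as.matrix(x) %*% beta
  ll <- 0
  for (i in seq_along(times)) {
    if (status[i] == 1) {
      risk <- times >= times[i]
      ll <- ll + eta[i] - log(sum(exp(eta[risk])))
    }
  }
  ll
}

# Independent unit-weight AHR score function: sum over events of
# w(t_i) * (x_i - weighted risk-set mean).  Solved by uniroot in tests.
enum_ahr_score <- function(beta, x, times, status, wt_of_time = function(t) 1) {
  s <- 0
  for (i in seq_along(times)) {
    if (status[i] == 1) {
      risk <- times >= times[i]
      r <- exp(beta * x[risk])
      s <- s + wt_of_time(times[i]) * (x[i] - sum(r * x[risk]) / sum(r))
    }
  }
  s
}
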