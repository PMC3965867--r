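# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately avoid the package's vectorized likelihood engine:
# they sum densities term by term and integrate on a fixed grid.

# a small hand-built subject with known numbers
make_subject <- function(id = "A",
                         age = 50, male = 1, single = 0, skin = 1,
                         lymphocyte = 30, follow_up = 12,
                         t = c(0, 3, 6), titer = c(20, 40, 80),
                         event_times = c(0, 5), delta_last = 0) {
  covs <- subject_covariates(age, male, single, skin, lymphocyte, follow_up)
  ep <- build_gap_times(event_times, follow_up)
  subject_data(id, covs, data.frame(t = t, titer = titer), ep)
}

# term-by-term normal log-density sum (independent of cond_loglik_long)
oracle_loglik_long <- function(subject, params, alpha) {
  ob <- subject$observations
  if (nrow(ob) == 0L) return(0)
  total <- 0
  for (j in seq_len(nrow(ob))) {
    x <- longitudinal_design_row(subject$covariates, ob$t[j])
    mu <- sum(x * params$beta) + alpha
    total <- total - 0.5 * log(2 * pi * params$sigma_e^2) -
      (ob$y[j] - mu)^2 / (2 * params$sigma_e^2)
  }
  total
}

# per-episode density/survivor oracle: event -> log(h * S), censored -> log S
oracle_loglik_rec <- function(subject, params, alpha,
                              scaling = reference_scaling()) {
  ep <- subject$episodes
  total <- 0
  for (k in seq_len(nrow(ep))) {
    s <- gap_survivor(params, subject$covariates, alpha, ep$w[k], scaling)
    if (ep$delta[k] == 1) {
      z <- recurrence_design_row(subject$covariates, scaling)
      h <- baseline_hazard_at(params$baseline, ep$w[k]) *
        exp(sum(z * params$eta) + params$gamma * alpha)
      total <- total + log(h * s)
    } else {
      total <- total + log(s)
    }
  }
  total
}

# brute-force trapezoid integration of the joint marginal over alpha
oracle_marginal <- function(subject, params, npt = 20000, width = 10,
                            scaling = reference_scaling()) {
  sa <- params$random_effect$sigma_alpha
  a <- seq(-width * sa, width * sa, length.out = npt)
  lg <- vapply(a, function(ai) {
    cond_loglik_long(subject, params$longitudinal, ai) +
      cond_loglik_rec(subject, params$recurrence, ai, scaling) +
      dnorm(ai, 0, sa, log = TRUE)
  }, numeric(1))
  m <- max(lg)
  m + log(sum(exp(lg - m)) * (a[2L] - a[1L]))
}
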