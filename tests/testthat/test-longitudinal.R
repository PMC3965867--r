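test_that("longitudinal design row has the documented order", {
  cv <- subject_covariates(50, 1, 0, 1, 30, 24)
  expect_equal(unname(longitudinal_design_row(cv, 0)),
               c(1, 50, 1, 0, 30, 0))
  expect_equal(unname(longitudinal_design_row(cv, 12)),
               c(1, 50, 1, 0, 30, 12))
  expect_error(longitudinal_design_row(cv, -1), ">= 0")
})

test_that("conditional log-likelihood is a sum of normal log-densities", {
  lp <- longitudinal_params(beta = c(0.5, 0.02, 1, 0.3, 0.04, 0.02),
                            sigma_e = 1)
  # one observation with zero residual at sigma_e = 1
  cv <- subject_covariates(40, 0, 0, 0, 20, 5)
  mu0 <- sum(longitudinal_design_row(cv, 0) * lp$beta)
  s <- subject_data("Z", cv,
                    data.frame(t = 0, titer = exp(mu0) - 1),
                    build_gap_times(0, 5))
  expect_equal(cond_loglik_long(s, lp, alpha = 0), -0.5 * log(2 * pi),
               tolerance = 1e-12)

  # additivity and agreement with the term-by-term oracle
  set.seed(5)
  for (i in 1:10) {
    subj <- make_subject(t = 0:7, titer = rexp(8, 1 / 50))
    a <- rnorm(1)
    lp2 <- longitudinal_params(rnorm(6, 0, 0.3), sigma_e = runif(1, 0.3, 2))
    expect_equal(cond_loglik_long(subj, lp2, a),
                 oracle_loglik_long(subj, lp2, a), tolerance = 1e-12)
  }
  expect_error(longitudinal_params(rep(0, 6), sigma_e = 0), "> 0")
})

test_that("closed-form marginal equals the compound-symmetry integral", {
  set.seed(6)
  lp <- longitudinal_params(c(0.4, 0.03, 1.3, 0.4, 0.04, 0.024), 0.6)

  # degenerate random effect: marginal reduces to conditional at alpha = 0
  subj <- make_subject(t = 0:5, titer = rexp(6, 1 / 40))
  expect_equal(marginal_loglik_long(subj, lp, random_effect_params(0)),
               cond_loglik_long(subj, lp, 0), tolerance = 1e-12)

  # single observation: variances add
  s1 <- make_subject(t = 2, titer = 30)
  lp1 <- longitudinal_params(lp$beta, sigma_e = 4)
  mu <- sum(longitudinal_design_row(s1$covariates, 2) * lp$beta)
  expect_equal(marginal_loglik_long(s1, lp1, random_effect_params(3)),
               dnorm(s1$observations$y, mu, 5, log = TRUE),
               tolerance = 1e-12)

  # trapezoid integration of exp(conditional) * normal density
  re <- random_effect_params(0.8)
  for (i in 1:5) {
    subj <- make_subject(t = 0:9, titer = rexp(10, 1 / 50))
    a <- seq(-8, 8, length.out = 10000)
    lg <- vapply(a, function(ai) {
      cond_loglik_long(subj, lp, ai) + dnorm(ai, 0, 0.8, log = TRUE)
    }, numeric(1))
    m <- max(lg)
    trap <- m + log(sum(exp(lg - m)) * (a[2] - a[1]))
    expect_equal(marginal_loglik_long(subj, lp, re), trap,
                 tolerance = 1e-8)
  }
})
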