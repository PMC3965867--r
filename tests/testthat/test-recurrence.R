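test_that("baseline hazards evaluate and integrate correctly", {
  # exponential special case and Weibull formula
  expect_equal(baseline_hazard_at(weibull_baseline(0.2, 1), 7), 0.2)
  expect_equal(baseline_hazard_at(weibull_baseline(0.1, 2), 3), 0.6)
  expect_equal(cumulative_baseline(weibull_baseline(0.2, 1), 5), 1.0)

  # piecewise lookup and area
  pw <- piecewise_baseline(c(0, 6), c(0.3, 0.1))
  expect_equal(baseline_hazard_at(pw, 8), 0.1)
  expect_equal(baseline_hazard_at(pw, 2), 0.3)
  expect_equal(cumulative_baseline(pw, 8), 0.3 * 6 + 0.1 * 2)
  expect_equal(cumulative_baseline(pw, 0), 0)

  expect_error(baseline_hazard_at(pw, 0), "> 0")
  expect_error(cumulative_baseline(pw, -1), ">= 0")
  expect_error(weibull_baseline(-1, 1), "> 0")
  expect_error(piecewise_baseline(c(1, 6), c(0.1, 0.2)), "start at 0")
})

test_that("cumulative hazard matches a dense numerical integral", {
  for (bl in list(weibull_baseline(0.08, 1.4),
                  piecewise_baseline(c(0, 4, 10), c(0.25, 0.12, 0.05)))) {
    w <- 13.7
    u <- seq(1e-9, w, length.out = 1e5)
    num <- sum(baseline_hazard_at(bl, u)) * (u[2] - u[1])
    expect_equal(cumulative_baseline(bl, w), num, tolerance = 1e-3)
    # inverse round-trip
    x <- c(0.05, 0.4, 1.7)
    expect_equal(cumulative_baseline(bl, inverse_cumulative_baseline(bl, x)),
                 x, tolerance = 1e-10)
  }
})

test_that("conditional recurrence log-likelihood matches first principles", {
  cv <- subject_covariates(47.5, 0, 0, 0, 30, 20)  # z-design all zero
  ep1 <- data.frame(k = 1, w = 4, delta = 1)
  s1 <- subject_data("E", cv, data.frame(t = numeric(0), titer = numeric(0)),
                     ep1)
  rp <- recurrence_params(rep(0, 4), gamma = 0,
                          baseline = weibull_baseline(0.25, 1))
  expect_equal(cond_loglik_rec(s1, rp, 0), log(0.25) - 1, tolerance = 1e-12)

  s2 <- subject_data("F", cv, data.frame(t = numeric(0), titer = numeric(0)),
                     data.frame(k = 1, w = 10, delta = 0))
  expect_equal(cond_loglik_rec(s2, rp, 0), -2.5, tolerance = 1e-12)

  # random subjects against the per-episode density/survivor oracle
  set.seed(8)
  for (i in 1:10) {
    subj <- make_subject(event_times = c(0, sort(runif(3, 1, 9))),
                         follow_up = 12)
    rp2 <- recurrence_params(rnorm(4, 0, 0.3), gamma = rnorm(1, 0, 0.5),
                             baseline = weibull_baseline(runif(1, 0.02, 0.3),
                                                         runif(1, 0.6, 1.8)))
    a <- rnorm(1)
    expect_equal(cond_loglik_rec(subj, rp2, a),
                 oracle_loglik_rec(subj, rp2, a), tolerance = 1e-12)
    # single-event identity exp(loglik) = h(w) S(w)
    w1 <- subj$episodes$w[1]
    se1 <- subject_data("G", subj$covariates,
                        data.frame(t = numeric(0), titer = numeric(0)),
                        data.frame(k = 1, w = w1, delta = 1))
    z <- recurrence_design_row(subj$covariates)
    h <- baseline_hazard_at(rp2$baseline, w1) *
      exp(sum(z * rp2$eta) + rp2$gamma * a)
    expect_equal(exp(cond_loglik_rec(se1, rp2, a)),
                 h * gap_survivor(rp2, subj$covariates, a, w1),
                 tolerance = 1e-12)
  }
})

test_that("gap survivor is a valid, proportional-hazards survivor", {
  cv <- subject_covariates(60, 1, 0, 1, 25, 30)
  rp <- recurrence_params(c(0.1, -0.1, 0.4, -0.08), gamma = 0.9,
                          baseline = weibull_baseline(0.1, 1.2))
  expect_equal(gap_survivor(rp, cv, 0.5, 0), 1)
  expect_equal(gap_survivor(recurrence_params(rep(0, 4), 0,
                                              weibull_baseline(0.1, 1)),
                            subject_covariates(47.5, 0, 0, 0, 30, 20),
                            0, 10),
               exp(-1), tolerance = 1e-12)
  w <- seq(0.5, 24, by = 0.5)
  s <- gap_survivor(rp, cv, 0.5, w)
  expect_true(all(s > 0 & s <= 1))
  expect_true(all(diff(s) < 0))

  # hazard ratio between two covariate patterns is constant in w
  cv2 <- subject_covariates(35, 0, 1, 0, 25, 30)
  for (bl in list(weibull_baseline(0.1, 1.6),
                  piecewise_baseline(c(0, 5), c(0.2, 0.08)))) {
    rpb <- recurrence_params(c(0.1, -0.1, 0.4, -0.08), 0.9, bl)
    h1 <- -log(gap_survivor(rpb, cv, 0, w))
    h2 <- -log(gap_survivor(rpb, cv2, 0, w))
    expect_equal(diff(range(h1 / h2)), 0, tolerance = 1e-10)
  }

  # adding log(2)/gamma to alpha doubles the cumulative-hazard exponent
  H1 <- -log(gap_survivor(rp, cv, 0.2, 12))
  H2 <- -log(gap_survivor(rp, cv, 0.2 + log(2) / rp$gamma, 12))
  expect_equal(H2 / H1, 2, tolerance = 1e-12)
})
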