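test_that("generator is deterministic given the RNG state", {
  cfg <- generator_config(n_subjects = 3)
  set.seed(99); s1 <- simulate_subject(cfg, "X")
  set.seed(99); s2 <- simulate_subject(cfg, "X")
  expect_identical(s1, s2)
  c1 <- simulate_cohort(generator_config(n_subjects = 5, seed = 123))
  c2 <- simulate_cohort(generator_config(n_subjects = 5, seed = 123))
  expect_identical(c1$subjects, c2$subjects)
  expect_equal(c1$metadata$seed, 123)
})

test_that("noise-free limit reproduces the linear predictor exactly", {
  truth <- default_paper_params()
  truth$longitudinal$sigma_e <- 1e-12   # constructors require > 0
  truth$random_effect$sigma_alpha <- 0
  cfg <- generator_config(n_subjects = 2, truth = truth, seed = 4)
  ch <- simulate_cohort(cfg)
  for (s in ch$subjects) {
    x <- vapply(s$observations$t, function(t) {
      sum(longitudinal_design_row(s$covariates, t) * truth$longitudinal$beta)
    }, numeric(1))
    expect_equal(s$observations$y, pmax(x, 0), tolerance = 1e-9)
  }
})

test_that("simulated cohorts pass validation and match the covariate model", {
  ch <- simulate_cohort(generator_config(seed = 21))
  expect_equal(nrow(validate_cohort(ch)), 0)
  expect_length(ch$subjects, 112)
  age <- vapply(ch$subjects, function(s) s$covariates$age, numeric(1))
  # mean age within 3 SE of the reference 47.5 (SD 15.98, n = 112)
  expect_lt(abs(mean(age) - 47.5), 3 * 15.98 / sqrt(112))
})

test_that("gap sampler reproduces the exponential-mean oracle", {
  set.seed(22)
  g <- jmrecur:::sample_gaps(1e5, weibull_baseline(0.05, 1), rel_risk = 1)
  expect_lt(abs(mean(g) - 20), 3 * 20 / sqrt(1e5))
})

test_that("first gaps follow the analytic survivor (Kaplan-Meier check)", {
  set.seed(23)
  truth <- default_paper_params()
  truth$recurrence$eta <- rep(0, 4)
  truth$recurrence$gamma <- 0
  lam <- truth$recurrence$baseline$rate
  ch <- simulate_cohort(generator_config(n_subjects = 2000, truth = truth))
  first <- t(vapply(ch$subjects, function(s) {
    c(w = s$episodes$w[1], d = s$episodes$delta[1])
  }, numeric(2)))
  km <- survival::survfit(survival::Surv(first[, 1], first[, 2]) ~ 1)
  ks <- summary(km, times = c(6, 12, 24))
  expect_true(all(abs(ks$surv - exp(-lam * c(6, 12, 24))) <
                    3 * ks$std.err + 0.005))
})

test_that("stronger association shortens gaps for a positive random effect", {
  # with alpha > 0 fixed, increasing gamma raises the hazard, so the mean
  # sampled gap must decrease monotonically over a gamma grid
  truth <- default_paper_params()
  means <- vapply(c(0, 0.5, 1, 1.5), function(g) {
    set.seed(24)   # common random numbers isolate the gamma effect
    rr <- exp(g * 1.0)
    mean(jmrecur:::sample_gaps(2e4, truth$recurrence$baseline, rr))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
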