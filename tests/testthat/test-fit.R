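test_that("joint fit converges and is a likelihood fixed point", {
  set.seed(40)
  ch <- simulate_cohort(generator_config(n_subjects = 60))
  fit <- fit_joint(ch, rule = quad_rule(9))
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$se)))
  expect_equal(fit$n_subjects, 60)
  expect_equal(fit$loglik,
               joint_loglik(ch, fit$estimates, quad_rule(9)),
               tolerance = 1e-8)

  # refitting from the optimum must not move the likelihood
  refit <- fit_joint(ch, init = fit$estimates, rule = quad_rule(9),
                     se = FALSE)
  expect_lt(abs(refit$loglik - fit$loglik), 1e-6)

  # estimates land in a plausible neighborhood of the generating truth
  est <- param_vector(fit$estimates)
  truth <- param_vector(default_paper_params())
  expect_lt(abs(est[["sigma_e"]] - truth[["sigma_e"]]), 0.05)
  expect_lt(abs(est[["gamma"]] - truth[["gamma"]]), 0.6)
})

test_that("degenerate inputs are rejected", {
  ch <- simulate_cohort(generator_config(n_subjects = 5, seed = 41))
  one <- new_cohort(ch$subjects[1])
  expect_error(fit_joint(one), "at least 2 subjects")
  no_events <- new_cohort(lapply(ch$subjects, function(s) {
    s$episodes <- data.frame(k = 1, w = s$covariates$follow_up, delta = 0)
    s
  }))
  expect_error(fit_joint(no_events), "recurrence event")
})

test_that("longitudinal SEs match the closed-form marginal information", {
  set.seed(42)
  ch <- simulate_cohort(generator_config(n_subjects = 150))
  fit <- fit_joint(ch, rule = quad_rule(9), fix_gamma = TRUE)
  expect_true(fit$converged)

  # independent oracle: FD information of the analytic compound-symmetry
  # marginal likelihood (no quadrature) at the fitted values, with the
  # raw-scale intercept mapped exactly as the fit reports it
  scl <- reference_scaling()
  est <- fit$estimates
  th_hat <- jmrecur:::internal_theta(est, scl)[1:8]
  negll_long <- function(th) {
    lp <- longitudinal_params(
      c(th[1] - th[2] * scl$age_center - th[5] * scl$lymph_center,
        th[2:6]),
      exp(th[7]))
    re <- random_effect_params(exp(th[8]))
    -sum(vapply(ch$subjects, marginal_loglik_long, numeric(1),
                params = lp, re = re))
  }
  H <- jmrecur:::fd_hessian(negll_long, th_hat)
  V <- solve(H)
  se_or <- sqrt(diag(V))
  se_or[7] <- est$longitudinal$sigma_e * se_or[7]
  se_or[8] <- est$random_effect$sigma_alpha * se_or[8]
  L <- c(1, -scl$age_center, 0, 0, -scl$lymph_center, 0, 0, 0)
  se_or[1] <- sqrt(drop(t(L) %*% V %*% L))
  expect_equal(unname(fit$se[1:8]), unname(se_or), tolerance = 1e-4)
})

test_that("standard errors are stable under step-size halving", {
  set.seed(43)
  ch <- simulate_cohort(generator_config(n_subjects = 50))
  fit <- fit_joint(ch, rule = quad_rule(9), se = FALSE)
  s1 <- standard_errors(fit$estimates, ch, quad_rule(9), step = 2e-4)
  s2 <- standard_errors(fit$estimates, ch, quad_rule(9), step = 1e-4)
  expect_true(s1$pd && s2$pd)
  expect_lt(max(abs(s1$se / s2$se - 1)), 1e-3)
})

test_that("piecewise-constant baseline fits end to end", {
  set.seed(44)
  truth <- default_paper_params()
  ch <- simulate_cohort(generator_config(n_subjects = 80, truth = truth))
  fit <- fit_joint(ch, baseline = "piecewise", knots = c(0, 6, 15),
                   rule = quad_rule(9), control = list(rel_tol = 1e-8))
  expect_true(fit$converged)
  rates <- fit$estimates$recurrence$baseline$rates
  expect_length(rates, 3)
  # a constant-hazard truth should yield roughly flat fitted rates
  expect_lt(max(rates) / min(rates), 3)
  expect_lt(abs(fit$estimates$recurrence$gamma - truth$recurrence$gamma),
            0.8)
})

test_that("Wald and likelihood-ratio tests of gamma agree on large data", {
  set.seed(45)
  ch <- simulate_cohort(generator_config(n_subjects = 1000))
  fit1 <- fit_joint(ch, rule = quad_rule(9), control = list(rel_tol = 1e-9))
  fit0 <- fit_joint(ch, rule = quad_rule(9), fix_gamma = TRUE, se = FALSE,
                    control = list(rel_tol = 1e-9))
  wald <- (fit1$estimates$recurrence$gamma /
             fit1$se[["gamma"]])^2
  lr <- 2 * (fit1$loglik - fit0$loglik)
  expect_true(fit1$converged && fit0$converged)
  expect_lt(abs(wald / lr - 1), 0.2)
})

test_that("pipeline writes fit, table and log artifacts", {
  dir <- withr::local_tempdir()
  res <- run_pipeline(dir, generator_config(n_subjects = 30, seed = 46),
                      rule = quad_rule(7), control = list(rel_tol = 1e-8))
  expect_true(all(file.exists(res$files)))
  expect_true(res$fit$converged)
  log <- readLines(res$files[["log"]])
  expect_true(any(grepl("seed: 46", log)))
  js <- jsonlite::read_json(res$files[["fit"]])
  expect_equal(js$n_subjects, 30)
})
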