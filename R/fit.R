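# Maximum-likelihood fitting of the joint model.

# ---- internal (centered) parameterization -------------------------------
# Same layout as flatten_params() but with the longitudinal intercept on
# the centered-design scale, and with gamma removed when it is fixed at 0.

internal_theta <- function(params, scaling, fix_gamma = FALSE) {
  th <- flatten_params(params)
  th[1L] <- th[1L] + th[2L] * scaling$age_center +
    th[5L] * scaling$lymph_center
  if (fix_gamma) th <- th[-13L]
  th
}

internal_to_params <- function(th, template, scaling, fix_gamma = FALSE) {
  if (fix_gamma) th <- append(th, 0, after = 12L)
  th[1L] <- th[1L] - th[2L] * scaling$age_center -
    th[5L] * scaling$lymph_center
  unflatten_params(unname(th), template)
}

# ---- numerical derivatives ----------------------------------------------

fd_gradient <- function(f, x, h = 1e-5 * (1 + abs(x))) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- h[i]
    g[i] <- (f(x + e) - f(x - e)) / (2 * h[i])
  }
  g
}

fd_hessian <- function(f, x, h = 2e-4 * (1 + abs(x))) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) {
      for (j in seq((i + 1L), p)) {
        ej <- numeric(p); ej[j] <- h[j]
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) -
             f(x - ei + ej) + f(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# ---- staged initialization ----------------------------------------------

# Longitudinal: OLS for beta on the centered design, then within/between
# moment estimators for sigma_e and sigma_alpha.
init_longitudinal <- function(prep) {
  keep <- prep$nobs > 0L
  fitb <- qr.coef(qr(prep$Xc), prep$y)
  fitb[is.na(fitb)] <- 0
  r <- prep$y - drop(prep$Xc %*% fitb)
  n_i <- prep$nobs[keep]
  rbar <- (sum_by_subject(r, prep$obs_subj, prep$S) / pmax(prep$nobs, 1))[keep]
  rss_w <- sum(r^2) - sum(n_i * rbar^2)
  dfw <- max(sum(n_i) - length(n_i), 1)
  s2e <- max(rss_w / dfw, 1e-4)
  s2a <- max(var(rbar) - s2e * mean(1 / n_i), 1e-4)
  list(beta_c = fitb, sigma_e = sqrt(s2e), sigma_alpha = sqrt(s2a))
}

# Recurrence at gamma = 0: Weibull AFT via survival::survreg converted to
# the proportional-hazards parameterization; piecewise rates by
# occurrence/exposure with eta from a Cox gap-time fit.
init_recurrence <- function(prep, baseline_family, knots) {
  df <- data.frame(w = prep$w, delta = prep$delta,
                   prep$Z[prep$epi_subj, , drop = FALSE])
  eta0 <- rep(0, 4)
  if (baseline_family == "weibull") {
    sr <- tryCatch(
      survival::survreg(survival::Surv(w, delta) ~ age + male + single +
                          skin_phenotype, data = df, dist = "weibull"),
      error = function(e) NULL)
    if (!is.null(sr) && all(is.finite(coef(sr))) && is.finite(sr$scale)) {
      p0 <- 1 / sr$scale
      eta0 <- -coef(sr)[-1L] / sr$scale
      lam0 <- exp(-coef(sr)[1L] / sr$scale)
    } else {
      lam0 <- sum(prep$delta) / sum(prep$w)
      p0 <- 1
    }
    list(eta = unname(eta0), baseline = weibull_baseline(max(lam0, 1e-8),
                                                         min(max(p0, 0.2), 5)))
  } else {
    cx <- tryCatch(
      survival::coxph(survival::Surv(w, delta) ~ age + male + single +
                        skin_phenotype, data = df),
      error = function(e) NULL)
    if (!is.null(cx) && all(is.finite(coef(cx)))) eta0 <- coef(cx)
    rr <- exp(drop(prep$Z %*% eta0))[prep$epi_subj]
    upper <- c(knots[-1L], Inf)
    rates <- vapply(seq_along(knots), function(j) {
      at_risk <- pmax(0, pmin(prep$w, upper[j]) - knots[j])
      ev <- sum(prep$delta[prep$w > knots[j] & prep$w <= upper[j]])
      max(ev, 0.5) / max(sum(at_risk * rr), 1e-8)
    }, numeric(1))
    list(eta = unname(eta0), baseline = piecewise_baseline(knots, rates))
  }
}

# ---- main fitting routine -----------------------------------------------

#' Fit the joint model by maximum likelihood
#'
#' Maximizes the Gauss-Hermite marginal joint log-likelihood over the
#' unconstrained parameterization of [flatten_params()]. Initialization
#' is staged: the longitudinal submodel is fitted first (least squares
#' plus moment estimators of the variance components), the recurrence
#' submodel is fitted at `gamma = 0` (Weibull accelerated-failure-time
#' fit converted to the proportional-hazards scale, or
#' occurrence/exposure rates for a piecewise baseline), and the joint
#' likelihood is then polished by quasi-Newton optimization
#' ([stats::nlminb()]). The fit is deterministic given data, starting
#' values and options.
#'
#' @param cohort A `jm_cohort` with at least 2 subjects and 1 observed
#'   recurrence.
#' @param init Optional [parameter_set()] of starting values; by default
#'   the staged initialization above is used.
#' @param baseline `"weibull"` (default) or `"piecewise"`.
#' @param knots Knots for a piecewise baseline (months, starting at 0).
#' @param rule A [quad_rule()]; order 15, adaptive, by default.
#' @param scaling A [reference_scaling()] object.
#' @param fix_gamma If `TRUE`, the association parameter is held at 0
#'   (independent-submodels fit, useful for likelihood-ratio tests).
#' @param se Compute observed-information standard errors (default
#'   `TRUE`); disable for large simulation studies where only point
#'   estimates are needed.
#' @param control List of optimizer controls: `rel_tol` (relative
#'   log-likelihood change, default 1e-10), `grad_tol` (gradient max-norm
#'   relative to `1 + |loglik|`, default 1e-5), `iter_max`, `eval_max`.
#' @return An object of class `jm_fit`: `estimates` (a [parameter_set()]
#'   on the reported scale), `se`, `vcov` (unconstrained scale),
#'   `loglik`, `converged`, `diagnostics`, counts, and the reporting
#'   table of [fit_table()].
#' @export
fit_joint <- function(cohort, init = NULL, baseline = c("weibull", "piecewise"),
                      knots = NULL, rule = quad_rule(15),
                      scaling = reference_scaling(), fix_gamma = FALSE,
                      se = TRUE, control = list()) {
  baseline <- match.arg(baseline)
  validate_cohort(cohort, stop_on_error = TRUE)
  if (length(cohort$subjects) < 2L) {
    stop("need at least 2 subjects to fit the joint model", call. = FALSE)
  }
  ctrl <- utils::modifyList(list(rel_tol = 1e-10, grad_tol = 1e-5,
                                 iter_max = 1000L, eval_max = 5000L),
                            control)
  prep <- prepare_cohort(cohort, scaling)
  if (sum(prep$delta) < 1) {
    stop("need at least one observed recurrence event", call. = FALSE)
  }
  if (baseline == "piecewise" && is.null(knots)) {
    knots <- c(0, stats::quantile(prep$w[prep$delta == 1],
                                  c(1 / 3, 2 / 3), names = FALSE))
  }

  if (is.null(init)) {
    il <- init_longitudinal(prep)
    ir <- init_recurrence(prep, baseline, knots)
    beta0 <- il$beta_c
    beta0[1L] <- beta0[1L] - beta0[2L] * scaling$age_center -
      beta0[5L] * scaling$lymph_center
    init <- parameter_set(
      longitudinal_params(beta0, il$sigma_e),
      random_effect_params(il$sigma_alpha),
      recurrence_params(ir$eta, gamma = 0, baseline = ir$baseline))
  } else {
    stopifnot(inherits(init, "jm_params"))
    if (init$recurrence$baseline$family != baseline) {
      stop("`init` baseline family disagrees with `baseline`", call. = FALSE)
    }
  }

  th0 <- internal_theta(init, scaling, fix_gamma)
  # hot path: parse theta without constructor/validation overhead
  fit_knots <- init$recurrence$baseline$knots
  n_base <- if (baseline == "weibull") 2L else length(fit_knots)
  off <- if (fix_gamma) 12L else 13L
  negll <- function(th) {
    bl <- if (baseline == "weibull") {
      structure(list(family = "weibull", rate = exp(th[off + 1L]),
                     shape = exp(th[off + 2L])),
                class = c("jm_baseline_weibull", "jm_baseline"))
    } else {
      structure(list(family = "piecewise", knots = fit_knots,
                     rates = exp(th[off + seq_len(n_base)])),
                class = c("jm_baseline_piecewise", "jm_baseline"))
    }
    v <- tryCatch(
      -sum(engine_loglik(prep, th[1:6], exp(th[7L]), exp(th[8L]),
                         th[9:12], if (fix_gamma) 0 else th[13L],
                         bl, rule)[prep$sum_order]),
      error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }

  opt <- nlminb(th0, negll,
                control = list(rel.tol = ctrl$rel_tol,
                               iter.max = ctrl$iter_max,
                               eval.max = ctrl$eval_max))
  par <- opt$par
  obj <- opt$objective
  grad <- fd_gradient(negll, par)
  grad_tol_abs <- ctrl$grad_tol * (1 + abs(obj))
  # nlminb can stop short on ill-conditioned problems ("false
  # convergence"); polish with safeguarded Newton steps on the FD
  # gradient/Hessian until the gradient criterion holds.
  polish <- 0L
  while (max(abs(grad)) >= grad_tol_abs && polish < 5L) {
    H <- fd_hessian(negll, par)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    repeat {
      cand <- par - lambda * step
      cobj <- negll(cand)
      if (cobj <= obj + 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-4) break
    }
    if (cobj > obj + 1e-12) break
    par <- cand
    obj <- cobj
    grad <- fd_gradient(negll, par)
    polish <- polish + 1L
  }
  loglik <- -obj
  grad_ok <- max(abs(grad)) < grad_tol_abs
  converged <- is.finite(loglik) &&
    (grad_ok || (opt$convergence == 0 && polish == 0L))
  opt$par <- par

  est <- internal_to_params(opt$par, init, scaling, fix_gamma)
  res <- structure(
    list(estimates = est, se = NULL, vcov = NULL, loglik = loglik,
         converged = converged,
         diagnostics = list(message = opt$message,
                            iterations = opt$iterations,
                            grad_max = max(abs(grad)), grad_ok = grad_ok,
                            fix_gamma = fix_gamma,
                            hessian_pd = NA),
         n_subjects = prep$S, n_obs = sum(prep$nobs),
         n_episodes = length(prep$w), n_events = sum(prep$delta),
         scaling = scaling, rule = rule, baseline = baseline,
         theta = opt$par),
    class = "jm_fit")

  if (se) {
    seinfo <- observed_information(negll, opt$par, est, scaling, fix_gamma)
    res$se <- seinfo$se
    res$vcov <- seinfo$vcov
    res$diagnostics$hessian_pd <- seinfo$pd
  }
  res
}

# SEs from the observed information: invert the FD Hessian of the
# negative log-likelihood (internal scale), then delta-map to reported
# scales (exp for log-parameters; the raw-scale intercept is a linear
# combination of centered-scale coefficients).
observed_information <- function(negll, theta, est, scaling, fix_gamma,
                                 step = 2e-4) {
  H <- fd_hessian(negll, theta, h = step * (1 + abs(theta)))
  V <- tryCatch(solve(H), error = function(e) NULL)
  pd <- !is.null(V) && all(diag(V) > 0)
  nm <- names(flatten_params(est))
  if (fix_gamma) nm <- nm[-13L]
  if (!pd) {
    return(list(se = setNames(rep(NA_real_, length(nm)), nm), vcov = V,
                pd = FALSE))
  }
  dimnames(V) <- list(nm, nm)
  se_int <- sqrt(diag(V))
  # delta method, internal -> reported
  th_flat <- flatten_params(est)
  if (fix_gamma) th_flat <- th_flat[-13L]
  se <- se_int
  logpar <- grepl("^log_", nm)
  se[logpar] <- exp(th_flat[logpar]) * se_int[logpar]
  names(se)[logpar] <- sub("^log_", "", nm[logpar])
  # intercept: beta0_raw = beta0_c - a0 * beta_age - l0 * beta_lym
  L <- numeric(length(nm))
  L[1L] <- 1
  L[2L] <- -scaling$age_center
  L[5L] <- -scaling$lymph_center
  se[1L] <- sqrt(drop(t(L) %*% V %*% L))
  list(se = se, vcov = V, pd = TRUE)
}

#' Observed-information standard errors at given parameter values
#'
#' Recomputes the numerically differentiated negative Hessian of
#' [joint_loglik()] at `params` and returns delta-method standard errors
#' on the reported scale together with the covariance of the
#' unconstrained parameterization. [fit_joint()] calls this internally;
#' exposing it separately allows SEs at externally supplied parameter
#' values.
#'
#' @param params A [parameter_set()] (typically a fitted optimum).
#' @param cohort The `jm_cohort` the likelihood is evaluated on.
#' @param rule A [quad_rule()].
#' @param scaling A [reference_scaling()] object.
#' @param fix_gamma Treat `gamma` as fixed at its current value.
#' @param step Relative central-difference step for the Hessian.
#' @return List with `se` (reported scale), `vcov` (unconstrained
#'   scale), and `pd` (Hessian positive-definite flag).
#' @export
standard_errors <- function(params, cohort, rule = quad_rule(15),
                            scaling = reference_scaling(),
                            fix_gamma = FALSE, step = 2e-4) {
  stopifnot(inherits(params, "jm_params"), inherits(cohort, "jm_cohort"))
  prep <- prepare_cohort(cohort, scaling)
  negll <- function(th) {
    p <- internal_to_params(th, params, scaling, fix_gamma)
    a <- engine_args(p, scaling)
    -sum(engine_loglik(prep, a$beta_c, a$sigma_e, a$sigma_alpha, a$eta,
                       a$gamma, a$baseline, rule)[prep$sum_order])
  }
  observed_information(negll, internal_theta(params, scaling, fix_gamma),
                       params, scaling, fix_gamma, step = step)
}
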