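# Vectorized marginal-likelihood engine.
#
# All subject-level quantities the joint likelihood needs reduce to a few
# per-subject scalars: with residuals r_ij = y_ij - x_ij' beta (centered
# design) the conditional longitudinal log-likelihood is a quadratic in
# alpha through n_i, sum(r) and sum(r^2); the conditional recurrence
# log-likelihood is B_i + gamma * D_i * alpha - A_i * exp(gamma * alpha)
# with D_i the event count, A_i the accumulated cumulative hazard times
# exp(z_i' eta) and B_i the event log-hazard terms. The log-integrand is
# therefore strictly concave in alpha, its mode is found by a vectorized
# safeguarded Newton iteration, and adaptive Gauss-Hermite quadrature is
# applied around mode and curvature simultaneously for all subjects.

# Stack a cohort into flat arrays once per fit.
prepare_cohort <- function(cohort, scaling = reference_scaling()) {
  subs <- cohort$subjects
  S <- length(subs)
  nobs <- vapply(subs, function(s) nrow(s$observations), integer(1))
  y <- unlist(lapply(subs, function(s) s$observations$y), use.names = FALSE)
  X <- do.call(rbind, lapply(subs, function(s) {
    longitudinal_design(s$covariates, s$observations$t)
  }))
  if (is.null(X)) X <- matrix(0, 0, 6)
  Xc <- X
  Xc[, 2L] <- Xc[, 2L] - scaling$age_center
  Xc[, 5L] <- Xc[, 5L] - scaling$lymph_center
  obs_subj <- rep.int(seq_len(S), nobs)

  nepi <- vapply(subs, function(s) nrow(s$episodes), integer(1))
  w <- unlist(lapply(subs, function(s) s$episodes$w), use.names = FALSE)
  delta <- unlist(lapply(subs, function(s) s$episodes$delta),
                  use.names = FALSE)
  epi_subj <- rep.int(seq_len(S), nepi)
  Z <- do.call(rbind, lapply(subs, function(s) {
    recurrence_design_row(s$covariates, scaling)
  }))
  ids <- vapply(subs, function(s) s$subject_id, character(1))
  list(S = S, ids = ids, sum_order = order(ids),
       y = y, X = X, Xc = Xc, nobs = nobs, obs_subj = obs_subj,
       obs_ends = cumsum(nobs), epi_ends = cumsum(nepi),
       w = w, logw = log(w), delta = delta, nepi = nepi,
       epi_subj = epi_subj, Z = Z,
       D = group_sum(delta, cumsum(nepi)),
       scaling = scaling)
}

# Per-subject sums of a stacked vector. Subjects are stored contiguously,
# so group sums are differences of the cumulative sum at group ends
# (zero-length groups yield 0).
group_sum <- function(v, ends) {
  cs <- c(0, cumsum(v))[ends + 1L]
  cs - c(0, cs[-length(cs)])
}

# kept for per-subject API paths where contiguity is not guaranteed
sum_by_subject <- function(v, idx, S) {
  out <- numeric(S)
  if (length(v)) {
    agg <- rowsum(v, idx, reorder = TRUE)
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

# Per-subject marginal log-likelihoods for a prepared cohort.
# `beta_c` is on the centered-design scale used by `prep$Xc`.
engine_loglik <- function(prep, beta_c, sigma_e, sigma_alpha, eta, gamma,
                          baseline, rule) {
  S <- prep$S
  s2e <- sigma_e^2
  s2a <- sigma_alpha^2
  r <- prep$y - drop(prep$Xc %*% beta_c)
  Sr <- group_sum(r, prep$obs_ends)
  Srr <- group_sum(r * r, prep$obs_ends)
  n_i <- prep$nobs
  constL <- -0.5 * n_i * log(2 * pi * s2e)

  if (baseline$family == "weibull") {
    lh0 <- log(baseline$rate) + log(baseline$shape) +
      (baseline$shape - 1) * prep$logw
    H0 <- baseline$rate * exp(baseline$shape * prep$logw)
  } else {
    lh0 <- log_baseline_hazard(baseline, prep$w)
    H0 <- cumulative_baseline(baseline, prep$w)
  }
  lpz <- drop(prep$Z %*% eta)
  A <- group_sum(H0, prep$epi_ends) * exp(lpz)
  B <- group_sum(prep$delta * lh0, prep$epi_ends) + prep$D * lpz
  D <- prep$D

  cond_sum <- function(a) {
    # works for a length-S vector or an S x K matrix (column recycling)
    ga <- pmin(gamma * a, 700)
    constL - (Srr - 2 * a * Sr + n_i * a * a) / (2 * s2e) +
      B + gamma * D * a - A * exp(ga)
  }

  if (s2a == 0) {
    return(cond_sum(numeric(S)))
  }

  g <- function(a) cond_sum(a) - a * a / (2 * s2a) - 0.5 * log(2 * pi * s2a)

  if (rule$adaptive) {
    # Newton for the mode of the strictly concave log-integrand
    a <- (Sr / s2e) / (n_i / s2e + 1 / s2a)   # exact when gamma = 0
    for (iter in seq_len(100L)) {
      ega <- exp(pmin(gamma * a, 700))
      g1 <- (Sr - n_i * a) / s2e + gamma * (D - A * ega) - a / s2a
      g2 <- -n_i / s2e - gamma^2 * A * ega - 1 / s2a
      step <- pmax(pmin(g1 / g2, 10), -10)
      a <- a - step
      if (max(abs(step)) < 1e-11) break
    }
    ega <- exp(pmin(gamma * a, 700))
    curv <- n_i / s2e + gamma^2 * A * ega + 1 / s2a
    mu <- a
    sd_i <- 1 / sqrt(curv)
  } else {
    mu <- numeric(S)
    sd_i <- rep(sigma_alpha, S)
  }

  Amat <- mu + outer(sd_i * sqrt(2), rule$nodes)
  G <- g(Amat)
  Gmax <- do.call(pmax, lapply(seq_len(ncol(G)), function(k) G[, k]))
  li <- log(sqrt(2) * sd_i) + Gmax +
    log(drop(exp(G - Gmax) %*% rule$mod_weights))
  if (any(!is.finite(li))) {
    bad <- prep$ids[!is.finite(li)][1L]
    stop("non-finite marginal likelihood for subject ", bad, call. = FALSE)
  }
  li
}

# split a parameter set into the engine's arguments, centering the
# intercept so beta_c matches the centered design
engine_args <- function(params, scaling) {
  beta <- params$longitudinal$beta
  beta_c <- beta
  beta_c[1L] <- beta[1L] + beta[2L] * scaling$age_center +
    beta[5L] * scaling$lymph_center
  list(beta_c = beta_c, sigma_e = params$longitudinal$sigma_e,
       sigma_alpha = params$random_effect$sigma_alpha,
       eta = params$recurrence$eta, gamma = params$recurrence$gamma,
       baseline = params$recurrence$baseline)
}

#' Marginal joint log-likelihood of a single subject
#'
#' Integrates the shared random intercept out of the product of the
#' conditional longitudinal and recurrence likelihoods,
#' \deqn{\ell_i = \log \int \exp\{\ell_i^{long}(\alpha) +
#'   \ell_i^{rec}(\alpha)\}\, \phi(\alpha; 0, \sigma_\alpha^2)\, d\alpha,}
#' by (adaptive) Gauss-Hermite quadrature, computed on the log scale with
#' max-subtraction for numerical stability. With `sigma_alpha = 0` the
#' mixing distribution is degenerate and the conditional log-likelihoods
#' at `alpha = 0` are returned.
#'
#' @param subject A [subject_data()] object.
#' @param params A [parameter_set()].
#' @param rule A [quad_rule()].
#' @param scaling A [reference_scaling()] object.
#' @return Marginal log-likelihood (scalar).
#' @export
subject_marginal_loglik <- function(subject, params, rule = quad_rule(),
                                    scaling = reference_scaling()) {
  stopifnot(inherits(subject, "jm_subject"), inherits(params, "jm_params"),
            inherits(rule, "jm_quad_rule"))
  prep <- prepare_cohort(new_cohort(list(subject)), scaling)
  a <- engine_args(params, scaling)
  unname(engine_loglik(prep, a$beta_c, a$sigma_e, a$sigma_alpha, a$eta,
                       a$gamma, a$baseline, rule)[1L])
}

#' Joint log-likelihood of a cohort
#'
#' Sum of [subject_marginal_loglik()] over subjects. Each subject's
#' contribution is evaluated independently and summation runs in sorted
#' subject-id order, so the value is bitwise invariant to how the cohort
#' is ordered. ([fit_joint()] uses an equivalent vectorized evaluation of
#' the same quantity internally.)
#'
#' @param cohort A `jm_cohort`.
#' @inheritParams subject_marginal_loglik
#' @return Log-likelihood (scalar).
#' @export
joint_loglik <- function(cohort, params, rule = quad_rule(),
                         scaling = reference_scaling()) {
  stopifnot(inherits(cohort, "jm_cohort"), inherits(params, "jm_params"))
  ids <- names(cohort$subjects)
  li <- vapply(cohort$subjects[order(ids)], subject_marginal_loglik,
               numeric(1), params = params, rule = rule, scaling = scaling)
  sum(li)
}
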