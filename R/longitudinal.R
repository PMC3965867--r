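#' Design row for the longitudinal submodel
#'
#' Fixed column order `(intercept, age, male, single, lymphocyte, time)`,
#' with age and lymphocyte on their raw scales and time in months since
#' disease onset.
#'
#' @param covariates A [subject_covariates()] object.
#' @param t Measurement time in months, `>= 0`.
#' @return Named numeric vector of length 6.
#' @export
longitudinal_design_row <- function(covariates, t) {
  if (!is.finite(t) || t < 0) {
    stop("measurement time must be finite and >= 0, got ", t, call. = FALSE)
  }
  drop(longitudinal_design(covariates, t))
}

# design matrix for a vector of times (rows share the subject's covariates)
longitudinal_design <- function(covariates, t) {
  cv <- covariates
  m <- cbind(`(Intercept)` = 1, age = cv$age, male = cv$male,
             single = cv$single, lymphocyte = cv$lymphocyte, time = t)
  m
}

#' Conditional longitudinal log-likelihood given the random intercept
#'
#' Sum over a subject's measurements of the normal log-density
#' `N(y_ij; x_ij' beta + alpha, sigma_e^2)`. A subject without
#' longitudinal measurements contributes 0.
#'
#' @param subject A [subject_data()] object.
#' @param params A [longitudinal_params()] object.
#' @param alpha Value of the shared random intercept.
#' @return Log-likelihood contribution (scalar).
#' @export
cond_loglik_long <- function(subject, params, alpha) {
  stopifnot(inherits(subject, "jm_subject"),
            inherits(params, "jm_long_params"))
  ob <- subject$observations
  if (nrow(ob) == 0L) return(0)
  x <- longitudinal_design(subject$covariates, ob$t)
  mu <- drop(x %*% params$beta) + alpha
  sum(dnorm(ob$y, mean = mu, sd = params$sigma_e, log = TRUE))
}

#' Closed-form marginal longitudinal log-likelihood
#'
#' With a single random intercept the subject's response vector is
#' multivariate normal with mean `X beta` and compound-symmetry
#' covariance `sigma_alpha^2 J + sigma_e^2 I`. The log-density has the
#' closed form (via the Sherman-Morrison identity)
#' \deqn{-\tfrac12\left[n\log 2\pi + (n-1)\log\sigma_e^2 +
#'   \log(\sigma_e^2 + n\sigma_\alpha^2) + \frac{1}{\sigma_e^2}
#'   \left(r'r - \frac{\sigma_\alpha^2 (\mathbf{1}'r)^2}
#'        {\sigma_e^2 + n\sigma_\alpha^2}\right)\right]}
#' with `r = y - X beta`. This is the analytic value the Gauss-Hermite
#' machinery must reproduce, and serves as the quadrature oracle.
#'
#' @inheritParams cond_loglik_long
#' @param re A [random_effect_params()] object.
#' @return Marginal log-likelihood contribution (scalar).
#' @export
marginal_loglik_long <- function(subject, params, re) {
  stopifnot(inherits(subject, "jm_subject"),
            inherits(params, "jm_long_params"),
            inherits(re, "jm_re_params"))
  ob <- subject$observations
  n <- nrow(ob)
  if (n == 0L) return(0)
  x <- longitudinal_design(subject$covariates, ob$t)
  r <- ob$y - drop(x %*% params$beta)
  s2e <- params$sigma_e^2
  s2a <- re$sigma_alpha^2
  denom <- s2e + n * s2a
  quad <- (sum(r^2) - s2a * sum(r)^2 / denom) / s2e
  -0.5 * (n * log(2 * pi) + (n - 1) * log(s2e) + log(denom) + quad)
}
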