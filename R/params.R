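#' Fixed covariate scaling used by the model's design matrices
#'
#' The recurrence submodel standardizes age as
#' `(age - age_center) / age_scale`, and the optimizer internally centers
#' the longitudinal age and lymphocyte columns at `age_center` and
#' `lymph_center` (centering is undone exactly before reporting, so all
#' longitudinal coefficients stay on their raw per-unit scales). The
#' defaults are the reference cohort's age mean 47.5 and SD 15.98 years
#' and a lymphocyte center of 30; fixing them (rather than recomputing
#' per dataset) makes simulated truth and fitted estimates live on
#' exactly the same scale.
#'
#' @param age_center,age_scale Center and scale for age (years).
#' @param lymph_center Center for the lymphocyte value.
#' @return A list of class `jm_scaling`.
#' @export
reference_scaling <- function(age_center = 47.5, age_scale = 15.98,
                              lymph_center = 30) {
  stopifnot(age_scale > 0)
  structure(list(age_center = age_center, age_scale = age_scale,
                 lymph_center = lymph_center),
            class = "jm_scaling")
}

#' Longitudinal submodel parameters
#'
#' @param beta Coefficient vector in the fixed order
#'   `(intercept, age, male, single, lymphocyte, time)`; per-unit effects
#'   on the `ln(1 + titer)` scale (age per year, time per month).
#' @param sigma_e Residual standard deviation, `> 0`.
#' @return A list of class `jm_long_params`.
#' @export
longitudinal_params <- function(beta, sigma_e) {
  beta <- as.numeric(beta)
  if (length(beta) != 6L || any(!is.finite(beta))) {
    stop("`beta` must be 6 finite coefficients ",
         "(intercept, age, male, single, lymphocyte, time)", call. = FALSE)
  }
  if (!is.finite(sigma_e) || sigma_e <= 0) {
    stop("`sigma_e` must be > 0", call. = FALSE)
  }
  names(beta) <- c("(Intercept)", "age", "male", "single", "lymphocyte",
                   "time")
  structure(list(beta = beta, sigma_e = as.numeric(sigma_e)),
            class = "jm_long_params")
}

#' Shared random-intercept distribution
#'
#' @param sigma_alpha Standard deviation of the shared random intercept
#'   `alpha ~ N(0, sigma_alpha^2)`, `>= 0` (0 collapses the model to
#'   independent submodels with no subject heterogeneity).
#' @return A list of class `jm_re_params`.
#' @export
random_effect_params <- function(sigma_alpha) {
  if (!is.finite(sigma_alpha) || sigma_alpha < 0) {
    stop("`sigma_alpha` must be >= 0", call. = FALSE)
  }
  structure(list(sigma_alpha = as.numeric(sigma_alpha)),
            class = "jm_re_params")
}

#' Weibull baseline hazard
#'
#' `h0(w) = rate * shape * w^(shape - 1)`, cumulative hazard
#' `H0(w) = rate * w^shape`. `shape = 1` gives the constant (exponential)
#' hazard `rate`.
#'
#' @param rate Scale parameter `lambda > 0` (per-month when `shape = 1`).
#' @param shape Shape parameter `p > 0`.
#' @return A list of class `c("jm_baseline_weibull", "jm_baseline")`.
#' @export
weibull_baseline <- function(rate, shape = 1) {
  if (!is.finite(rate) || rate <= 0 || !is.finite(shape) || shape <= 0) {
    stop("Weibull `rate` and `shape` must be > 0", call. = FALSE)
  }
  structure(list(family = "weibull", rate = as.numeric(rate),
                 shape = as.numeric(shape)),
            class = c("jm_baseline_weibull", "jm_baseline"))
}

#' Piecewise-constant baseline hazard
#'
#' The hazard equals `rates[j]` on `[knots[j], knots[j + 1])`; the last
#' piece extends to infinity.
#'
#' @param knots Strictly increasing cut points starting at 0 (months).
#' @param rates Positive hazard rates, one per piece (`length(knots)`).
#' @return A list of class `c("jm_baseline_piecewise", "jm_baseline")`.
#' @export
piecewise_baseline <- function(knots, rates) {
  knots <- as.numeric(knots); rates <- as.numeric(rates)
  if (length(knots) < 1L || knots[1L] != 0 || any(diff(knots) <= 0)) {
    stop("`knots` must be strictly increasing and start at 0", call. = FALSE)
  }
  if (length(rates) != length(knots) || any(!is.finite(rates) | rates <= 0)) {
    stop("`rates` must be positive, one per piece", call. = FALSE)
  }
  structure(list(family = "piecewise", knots = knots, rates = rates),
            class = c("jm_baseline_piecewise", "jm_baseline"))
}

#' Recurrent-event submodel parameters
#'
#' @param eta Coefficient vector on the log-hazard scale in the fixed
#'   order `(age, male, single, skin_phenotype)`; age enters standardized
#'   (see [reference_scaling()]), so `eta[1]` is per SD of age.
#' @param gamma Association parameter multiplying the shared random
#'   intercept in the log hazard; `gamma = 0` decouples the submodels.
#' @param baseline A [weibull_baseline()] or [piecewise_baseline()].
#' @return A list of class `jm_rec_params`.
#' @export
recurrence_params <- function(eta, gamma, baseline) {
  eta <- as.numeric(eta)
  if (length(eta) != 4L || any(!is.finite(eta))) {
    stop("`eta` must be 4 finite coefficients ",
         "(age, male, single, skin_phenotype)", call. = FALSE)
  }
  if (!is.finite(gamma)) stop("`gamma` must be finite", call. = FALSE)
  stopifnot(inherits(baseline, "jm_baseline"))
  names(eta) <- c("age", "male", "single", "skin_phenotype")
  structure(list(eta = eta, gamma = as.numeric(gamma), baseline = baseline),
            class = "jm_rec_params")
}

#' Full joint-model parameter set
#'
#' @param longitudinal A [longitudinal_params()] object.
#' @param random_effect A [random_effect_params()] object.
#' @param recurrence A [recurrence_params()] object.
#' @return A list of class `jm_params`.
#' @export
parameter_set <- function(longitudinal, random_effect, recurrence) {
  stopifnot(inherits(longitudinal, "jm_long_params"),
            inherits(random_effect, "jm_re_params"),
            inherits(recurrence, "jm_rec_params"))
  structure(list(longitudinal = longitudinal, random_effect = random_effect,
                 recurrence = recurrence),
            class = "jm_params")
}

#' @export
print.jm_params <- function(x, ...) {
  cat("Joint-model parameter set\n")
  cat("  longitudinal beta:",
      paste(sprintf("%s=%.4g", names(x$longitudinal$beta),
                    x$longitudinal$beta), collapse = " "), "\n")
  cat(sprintf("  sigma_e=%.4g  sigma_alpha=%.4g  gamma=%.4g\n",
              x$longitudinal$sigma_e, x$random_effect$sigma_alpha,
              x$recurrence$gamma))
  cat("  recurrence eta:",
      paste(sprintf("%s=%.4g", names(x$recurrence$eta), x$recurrence$eta),
            collapse = " "), "\n")
  b <- x$recurrence$baseline
  if (b$family == "weibull") {
    cat(sprintf("  baseline: Weibull(rate=%.4g, shape=%.4g)\n",
                b$rate, b$shape))
  } else {
    cat("  baseline: piecewise, knots", paste(b$knots, collapse = ","),
        "rates", paste(signif(b$rates, 4), collapse = ","), "\n")
  }
  invisible(x)
}

#' Flatten a parameter set to the unconstrained optimization vector
#'
#' The fixed flattening order is: the six longitudinal coefficients,
#' `log(sigma_e)`, `log(sigma_alpha)`, the four recurrence coefficients,
#' `gamma`, then the baseline-hazard parameters on the log scale
#' (`log(rate), log(shape)` for Weibull; `log(rates)` for a
#' piecewise-constant baseline, whose knots are structural and not
#' estimated). All strictly positive parameters are log-transformed so
#' the vector is unconstrained.
#'
#' @param params A [parameter_set()].
#' @return Named numeric vector.
#' @seealso [unflatten_params()]
#' @export
flatten_params <- function(params) {
  stopifnot(inherits(params, "jm_params"))
  b <- params$recurrence$baseline
  base <- if (b$family == "weibull") {
    c(log_rate = log(b$rate), log_shape = log(b$shape))
  } else {
    setNames(log(b$rates), paste0("log_rate", seq_along(b$rates)))
  }
  c(setNames(params$longitudinal$beta,
             paste0("beta.", names(params$longitudinal$beta))),
    log_sigma_e = log(params$longitudinal$sigma_e),
    log_sigma_alpha = log(params$random_effect$sigma_alpha),
    setNames(params$recurrence$eta,
             paste0("eta.", names(params$recurrence$eta))),
    gamma = params$recurrence$gamma,
    base)
}

#' Rebuild a parameter set from an unconstrained vector
#'
#' @param theta Numeric vector in the order documented in
#'   [flatten_params()].
#' @param template A [parameter_set()] supplying the baseline-hazard
#'   family (and knots, for a piecewise baseline).
#' @return A [parameter_set()].
#' @export
unflatten_params <- function(theta, template) {
  stopifnot(inherits(template, "jm_params"))
  b <- template$recurrence$baseline
  n_base <- if (b$family == "weibull") 2L else length(b$rates)
  if (length(theta) != 13L + n_base) {
    stop("`theta` has length ", length(theta), ", expected ", 13L + n_base,
         call. = FALSE)
  }
  baseline <- if (b$family == "weibull") {
    weibull_baseline(rate = exp(theta[14L]), shape = exp(theta[15L]))
  } else {
    piecewise_baseline(b$knots, exp(theta[13L + seq_len(n_base)]))
  }
  parameter_set(
    longitudinal_params(beta = theta[1:6], sigma_e = exp(theta[7L])),
    random_effect_params(sigma_alpha = exp(theta[8L])),
    recurrence_params(eta = theta[9:12], gamma = theta[13L],
                      baseline = baseline))
}

#' Natural-scale parameter vector
#'
#' Convenience view of a parameter set as a named vector on the reported
#' (natural) scale: coefficients as-is, standard deviations and baseline
#' parameters untransformed. Used by [recovery_study()] to compare
#' estimates with simulation truth.
#'
#' @param params A [parameter_set()].
#' @return Named numeric vector.
#' @export
param_vector <- function(params) {
  stopifnot(inherits(params, "jm_params"))
  b <- params$recurrence$baseline
  base <- if (b$family == "weibull") {
    c(rate = b$rate, shape = b$shape)
  } else {
    setNames(b$rates, paste0("rate", seq_along(b$rates)))
  }
  c(setNames(params$longitudinal$beta,
             paste0("beta.", names(params$longitudinal$beta))),
    sigma_e = params$longitudinal$sigma_e,
    sigma_alpha = params$random_effect$sigma_alpha,
    setNames(params$recurrence$eta,
             paste0("eta.", names(params$recurrence$eta))),
    gamma = params$recurrence$gamma,
    base)
}
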