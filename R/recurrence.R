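#' Baseline hazard at a gap time
#'
#' @param baseline A [weibull_baseline()] or [piecewise_baseline()].
#' @param w Gap times in months, each `> 0`.
#' @return Hazard rate(s) `h0(w)`.
#' @export
baseline_hazard_at <- function(baseline, w) {
  stopifnot(inherits(baseline, "jm_baseline"))
  if (any(!is.finite(w) | w <= 0)) {
    stop("gap time must be finite and > 0", call. = FALSE)
  }
  exp(log_baseline_hazard(baseline, w))
}

# log h0(w); vectorized over w
log_baseline_hazard <- function(baseline, w) {
  if (baseline$family == "weibull") {
    log(baseline$rate) + log(baseline$shape) +
      (baseline$shape - 1) * log(w)
  } else {
    piece <- findInterval(w, baseline$knots)
    log(baseline$rates[piece])
  }
}

#' Cumulative baseline hazard
#'
#' `H0(w) = integral of h0 from 0 to w`: `rate * w^shape` for the Weibull
#' family, and the rate-weighted overlap of `[0, w]` with each piece for a
#' piecewise-constant baseline. Continuous, nondecreasing, `H0(0) = 0`.
#'
#' @inheritParams baseline_hazard_at
#' @param w Gap times in months, each `>= 0`.
#' @return Cumulative hazard(s).
#' @export
cumulative_baseline <- function(baseline, w) {
  stopifnot(inherits(baseline, "jm_baseline"))
  if (any(!is.finite(w) | w < 0)) {
    stop("gap time must be finite and >= 0", call. = FALSE)
  }
  if (baseline$family == "weibull") {
    baseline$rate * w^baseline$shape
  } else {
    k <- baseline$knots
    upper <- c(k[-1L], Inf)
    vapply(w, function(wi) {
      sum(baseline$rates * pmax(0, pmin(wi, upper) - k))
    }, numeric(1))
  }
}

#' Invert the cumulative baseline hazard
#'
#' Solves `H0(w) = x` for `w`; used by the inverse-transform gap-time
#' sampler of [simulate_subject()].
#'
#' @inheritParams baseline_hazard_at
#' @param x Cumulative-hazard values, each `>= 0`.
#' @return Gap times `w` with `cumulative_baseline(baseline, w) = x`.
#' @export
inverse_cumulative_baseline <- function(baseline, x) {
  stopifnot(inherits(baseline, "jm_baseline"))
  if (any(!is.finite(x) | x < 0)) {
    stop("cumulative hazard must be finite and >= 0", call. = FALSE)
  }
  if (baseline$family == "weibull") {
    (x / baseline$rate)^(1 / baseline$shape)
  } else {
    k <- baseline$knots
    width <- diff(c(k, Inf))
    Hk <- c(0, cumsum(baseline$rates * width)[-length(k)])  # H0 at knots
    vapply(x, function(xi) {
      piece <- findInterval(xi, Hk)
      k[piece] + (xi - Hk[piece]) / baseline$rates[piece]
    }, numeric(1))
  }
}

#' Design row for the recurrence submodel
#'
#' Fixed order `(age, male, single, skin_phenotype)` with age
#' standardized by the fixed reference constants of
#' [reference_scaling()].
#'
#' @param covariates A [subject_covariates()] object.
#' @param scaling A [reference_scaling()] object.
#' @return Named numeric vector of length 4.
#' @export
recurrence_design_row <- function(covariates, scaling = reference_scaling()) {
  cv <- covariates
  c(age = (cv$age - scaling$age_center) / scaling$age_scale,
    male = cv$male, single = cv$single,
    skin_phenotype = cv$skin_phenotype)
}

#' Conditional recurrent-event log-likelihood given the random intercept
#'
#' With subject-level relative risk `c_i = exp(z_i' eta + gamma * alpha)`
#' each episode contributes
#' `delta_ik * (log h0(w_ik) + log c_i) - H0(w_ik) * c_i`: the log hazard
#' at an observed recurrence plus the log survivor probability of the gap
#' (gaps are conditionally independent renewals given `alpha`).
#'
#' @param subject A [subject_data()] object.
#' @param params A [recurrence_params()] object.
#' @param alpha Value of the shared random intercept.
#' @param scaling A [reference_scaling()] object.
#' @return Log-likelihood contribution (scalar).
#' @export
cond_loglik_rec <- function(subject, params, alpha,
                            scaling = reference_scaling()) {
  stopifnot(inherits(subject, "jm_subject"),
            inherits(params, "jm_rec_params"))
  ep <- subject$episodes
  z <- recurrence_design_row(subject$covariates, scaling)
  lp <- sum(z * params$eta) + params$gamma * alpha
  lh0 <- log_baseline_hazard(params$baseline, ep$w)
  H0 <- cumulative_baseline(params$baseline, ep$w)
  sum(ep$delta * (lh0 + lp) - H0 * exp(lp))
}

#' Conditional survivor function of a gap time
#'
#' `S_i(w | alpha) = exp(-H0(w) * c_i)` with
#' `c_i = exp(z_i' eta + gamma * alpha)`; equals 1 at `w = 0` and is
#' nonincreasing in `w`.
#'
#' @inheritParams cond_loglik_rec
#' @param covariates A [subject_covariates()] object.
#' @param w Gap times in months, each `>= 0`.
#' @return Survivor probabilities in `(0, 1]`.
#' @export
gap_survivor <- function(params, covariates, alpha, w,
                         scaling = reference_scaling()) {
  stopifnot(inherits(params, "jm_rec_params"))
  z <- recurrence_design_row(covariates, scaling)
  lp <- sum(z * params$eta) + params$gamma * alpha
  exp(-cumulative_baseline(params$baseline, w) * exp(lp))
}
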