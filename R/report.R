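# Reporting transforms and publication-style output.

#' Wald confidence interval
#'
#' `estimate +/- z * se` with `z` the standard-normal quantile for the
#' requested two-sided level (1.959964 at 95%).
#'
#' @param estimate Point estimate (coefficient scale).
#' @param se Standard error, `> 0`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' wald_ci(0.106, 0.417)   # (-0.711, 0.923) to 3 decimals
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  if (!is.finite(se) || se <= 0) stop("`se` must be > 0", call. = FALSE)
  if (!is.finite(level) || level <= 0 || level >= 1) {
    stop("`level` must be in (0, 1)", call. = FALSE)
  }
  z <- qnorm((1 + level) / 2)
  c(lower = estimate - z * se, upper = estimate + z * se)
}

#' Hazard ratio of a log-hazard coefficient
#'
#' @param coef Coefficient on the log-hazard scale.
#' @return `exp(coef)`.
#' @examples
#' hazard_ratio(0.367)    # 1.44: single vs married
#' hazard_ratio(-0.111)   # 0.895: male vs female
#' @export
hazard_ratio <- function(coef) {
  stopifnot(is.numeric(coef), all(is.finite(coef)))
  exp(coef)
}

#' Percent change per unit time on the log-response scale
#'
#' For a coefficient `b` of time in the model for `ln(1 + titer)`, the
#' quantity `1 + titer` is multiplied by `exp(b)` each month, i.e.
#' changes by `100 * (exp(b) - 1)` percent.
#'
#' @param coef Time coefficient on the log-response scale.
#' @return Percent change per unit time.
#' @examples
#' percent_change_per_unit(0.024)   # 2.43% per month
#' @export
percent_change_per_unit <- function(coef) {
  stopifnot(is.numeric(coef), all(is.finite(coef)))
  100 * expm1(coef)
}

#' Reporting table for a fitted joint model
#'
#' Rows in the fixed publication order: the longitudinal block
#' (intercept, age, male, single, lymphocyte, time), the recurrent-event
#' block (age, male, single, skin_phenotype), the association parameter
#' `gamma`, then the variance and baseline-hazard parameters. Wald
#' p-values and confidence bounds are given for regression coefficients
#' and `gamma` (positive parameters get log-scale intervals and no
#' p-value), plus a transformed column: hazard ratios for the
#' recurrent-event coefficients and the percent change per month for the
#' time coefficient.
#'
#' @param fit A `jm_fit` object.
#' @param level Confidence level, default 0.95.
#' @return Data frame with columns `block`, `term`, `estimate`, `se`,
#'   `p_value`, `lower`, `upper`, `transform`, `transform_value`.
#' @export
fit_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "jm_fit"))
  est <- param_vector(fit$estimates)
  se <- fit$se
  z <- qnorm((1 + level) / 2)
  nm <- names(est)
  blocks <- c(rep("longitudinal", 6), "variance", "variance",
              rep("recurrent", 4), "association",
              rep("baseline", length(est) - 13L))
  rows <- lapply(seq_along(est), function(i) {
    e <- est[i]
    s <- if (is.null(se)) NA_real_ else unname(se[i])
    positive <- blocks[i] %in% c("variance", "baseline")
    if (is.na(s)) {
      p <- lo <- hi <- NA_real_
    } else if (positive) {
      # log-scale interval back-transformed; Wald p not meaningful here
      sl <- s / e
      lo <- e * exp(-z * sl); hi <- e * exp(z * sl)
      p <- NA_real_
    } else {
      ci <- wald_ci(e, s, level)
      lo <- ci[1L]; hi <- ci[2L]
      p <- 2 * pnorm(-abs(e / s))
    }
    trans <- NA_character_; tv <- NA_real_
    if (blocks[i] %in% c("recurrent", "association")) {
      trans <- "HR"; tv <- hazard_ratio(e)
    } else if (nm[i] == "beta.time") {
      trans <- "pct/month"; tv <- percent_change_per_unit(e)
    }
    data.frame(block = blocks[i], term = sub("^(beta|eta)\\.", "", nm[i]),
               estimate = unname(e), se = s, p_value = p,
               lower = unname(lo), upper = unname(hi),
               transform = trans, transform_value = tv)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$block, c("longitudinal", "recurrent",
                                      "association", "variance",
                                      "baseline"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.jm_fit <- function(x, digits = 3, ...) {
  cat("Joint model: longitudinal ln(1 + titer) + recurrent gap times\n")
  cat(sprintf("  %d subjects, %d measurements, %d episodes (%d events)\n",
              x$n_subjects, x$n_obs, x$n_episodes, x$n_events))
  cat(sprintf("  log-likelihood %.3f, %s (baseline: %s, GH order %d%s)\n",
              x$loglik,
              if (x$converged) "converged" else "NOT CONVERGED",
              x$baseline, x$rule$order,
              if (x$rule$adaptive) ", adaptive" else ""))
  tab <- fit_table(x)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, digits))
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.jm_fit <- function(object, level = 0.95, ...) {
  structure(list(fit = object, table = fit_table(object, level)),
            class = "summary.jm_fit")
}

#' @export
print.summary.jm_fit <- function(x, ...) {
  print(x$fit, ...)
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes estimates (natural and unconstrained scale), standard errors,
#' the reporting table, log-likelihood, convergence diagnostics and
#' counts at full numeric precision.
#'
#' @param fit A `jm_fit` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "jm_fit"))
  payload <- list(
    estimates = as.list(param_vector(fit$estimates)),
    theta_unconstrained = as.list(flatten_params(fit$estimates)),
    se = if (is.null(fit$se)) NULL else as.list(fit$se),
    loglik = fit$loglik,
    converged = fit$converged,
    diagnostics = fit$diagnostics[c("message", "iterations", "grad_max")],
    n_subjects = fit$n_subjects, n_obs = fit$n_obs,
    n_episodes = fit$n_episodes, n_events = fit$n_events,
    baseline = fit$baseline,
    quadrature = list(order = fit$rule$order, adaptive = fit$rule$adaptive),
    table = fit_table(fit))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
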