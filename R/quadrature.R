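#' Gauss-Hermite quadrature rule for the shared random intercept
#'
#' Standard Gauss-Hermite abscissae and weights (weight function
#' `exp(-x^2)`), optionally used adaptively: the integrand is recentered
#' at its per-subject mode and rescaled by the local curvature before the
#' nodes are applied, which keeps a modest number of nodes accurate even
#' when the conditional posterior of `alpha` is much narrower than its
#' prior. With `adaptive = FALSE` the nodes are centered at 0 and scaled
#' by the prior SD `sigma_alpha`.
#'
#' @param order Number of nodes, `>= 3` (default 15).
#' @param adaptive Recenter/rescale per subject (default `TRUE`).
#' @return A list of class `jm_quad_rule` with `order`, `nodes`,
#'   `weights`, `adaptive`, and `mod_weights = weights * exp(nodes^2)`
#'   (the modified weights of the recentered formulation).
#' @export
quad_rule <- function(order = 15, adaptive = TRUE) {
  if (!is.numeric(order) || length(order) != 1L || order < 3) {
    stop("`order` must be an integer >= 3", call. = FALSE)
  }
  gh <- pracma::gaussHermite(as.integer(order))
  structure(list(order = as.integer(order), nodes = gh$x, weights = gh$w,
                 mod_weights = gh$w * exp(gh$x^2),
                 adaptive = isTRUE(adaptive)),
            class = "jm_quad_rule")
}

#' @export
print.jm_quad_rule <- function(x, ...) {
  cat("Gauss-Hermite rule: order ", x$order,
      if (x$adaptive) " (adaptive)" else " (prior-scaled)", "\n", sep = "")
  invisible(x)
}
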