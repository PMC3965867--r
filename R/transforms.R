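#' Log-transform a raw antibody titer
#'
#' The biomarker response modelled by the longitudinal submodel is
#' `ln(1 + titer)`: because many raw titers are exactly zero, one is added
#' before taking the natural logarithm. The transform is strictly
#' increasing, maps 0 to 0 and is inverted by [inverse_transform()].
#'
#' @param titer Numeric vector of raw titers, each finite and `>= 0`.
#' @return `log(1 + titer)`, same length as the input.
#' @examples
#' transform_titer(c(0, 99))          # 0 and log(100)
#' transform_titer(exp(1) - 1)        # exactly 1
#' @seealso [inverse_transform()]
#' @export
transform_titer <- function(titer) {
  if (!is.numeric(titer)) {
    stop("`titer` must be numeric", call. = FALSE)
  }
  bad <- !is.finite(titer) | titer < 0
  if (any(bad)) {
    stop("titers must be finite and non-negative; offending value(s): ",
         paste(utils::head(titer[bad], 5L), collapse = ", "), call. = FALSE)
  }
  log1p(titer)
}

#' Invert the titer log-transform
#'
#' Maps a transformed response `y = ln(1 + titer)` back to the raw titer
#' scale, `exp(y) - 1`. Round-trips with [transform_titer()] to floating
#' point accuracy.
#'
#' @param y Numeric vector, each element finite and `>= 0`.
#' @return Raw titers `exp(y) - 1`.
#' @export
inverse_transform <- function(y) {
  if (!is.numeric(y)) {
    stop("`y` must be numeric", call. = FALSE)
  }
  bad <- !is.finite(y) | y < 0
  if (any(bad)) {
    stop("transformed responses must be finite and non-negative; ",
         "offending value(s): ",
         paste(utils::head(y[bad], 5L), collapse = ", "), call. = FALSE)
  }
  expm1(y)
}
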