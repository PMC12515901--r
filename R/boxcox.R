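#' Box-Cox power transformation
#'
#' The one-parameter Box-Cox family maps positive data toward normality:
#' \eqn{(x^\lambda - 1)/\lambda} for \eqn{\lambda \neq 0} and \eqn{\log x}
#' at \eqn{\lambda = 0}. It is the model family used both by the synthetic
#' cohort generator (the healthy component is Gaussian on the transformed
#' scale) and by the inverse reference-interval estimator.
#'
#' Powers with absolute value below `1e-8` are treated as exactly zero so
#' the log branch is taken; the family is continuous in `lambda` so this
#' threshold only avoids catastrophic cancellation.
#'
#' @param x Numeric vector of strictly positive values.
#' @param lambda Transformation power (scalar).
#' @return `box_cox()`: the transformed values. `inverse_box_cox()`: the
#'   back-transformed positive values.
#' @examples
#' box_cox(exp(1), 0)          # 1
#' inverse_box_cox(box_cox(3.7, 0.4), 0.4)
#' @export
box_cox <- function(x, lambda) {
  stopifnot(is.numeric(x), length(lambda) == 1L, is.finite(lambda))
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("box_cox: all values must be finite and > 0")
  }
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

#' @rdname box_cox
#' @param y Numeric vector on the transformed scale.
#' @export
inverse_box_cox <- function(y, lambda) {
  stopifnot(is.numeric(y), length(lambda) == 1L, is.finite(lambda))
  if (abs(lambda) < 1e-8) {
    return(exp(y))
  }
  z <- lambda * y + 1
  if (any(z <= 0)) {
    stop("inverse_box_cox: value outside the range of the forward map ",
         "(lambda*y + 1 must be > 0)")
  }
  z^(1 / lambda)
}
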