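#' Least-squares polynomial curve fitting (PCF)
#'
#' Fits the polynomial of the given degree minimising the residual sum of
#' squares, by solving the normal equations obtained from setting the partial
#' derivatives with respect to each coefficient to zero. The residual vector
#' is therefore orthogonal to every monomial basis column. With
#' `degree = n - 1` the fit interpolates all points; higher degrees are
#' refused as underdetermined.
#'
#' @param ts a [trajectory_series()].
#' @param degree polynomial degree, `1 <= degree <= n - 1`. The package
#'   default for the five-point study series is 3: one degree below
#'   interpolation, so the points scatter around the curve instead of pinning
#'   it.
#' @return a fitted model of class `c("pcf_model", "proxy_model")` with
#'   `coefficients` (ascending powers), `degree`, `residuals`.
#' @examples
#' ts <- trajectory_series(0:4, c(1, 3, 2, 5, 4))
#' m <- fit_pcf(ts, degree = 3)
#' predict(m, 2.5)
#' @export
fit_pcf <- function(ts, degree = 3L) {
  stopifnot(inherits(ts, "trajectory_series"))
  n <- length(ts$x)
  assert_that(is_number(degree) && degree == round(degree) && degree >= 1,
              "degree must be a positive integer")
  assert_that(degree <= n - 1,
              "degree %d with %d points is underdetermined (max %d)",
              degree, n, n - 1)
  V <- outer(ts$x, 0:degree, `^`)
  # QR factorisation solves the same normal equations as the explicit
  # crossprod system, without squaring the Vandermonde condition number
  beta <- as.numeric(qr.coef(qr(V), ts$y))
  structure(list(kind = "PCF", coefficients = beta, degree = as.integer(degree),
                 x = ts$x, y = ts$y, residuals = ts$y - as.numeric(V %*% beta),
                 domain = range(ts$x), x_axis = ts$x_axis),
            class = c("pcf_model", "proxy_model"))
}

# Horner evaluation, ascending coefficients.
pcf_eval <- function(model, x) {
  b <- model$coefficients
  out <- rep(b[length(b)], length(x))
  for (k in rev(seq_len(length(b) - 1))) out <- out * x + b[k]
  out
}
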