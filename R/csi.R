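#' Natural cubic spline interpolation (CSI)
#'
#' Fits the C2-continuous piecewise-cubic interpolant through all training
#' points whose value, first and second derivative agree from the left and
#' right at every interior knot, and whose second derivative vanishes at both
#' end knots (the natural boundary condition). The interior second
#' derivatives solve the standard tridiagonal system, here by the Thomas
#' algorithm.
#'
#' @param ts a [trajectory_series()] with at least 3 points.
#' @return a fitted model of class `c("csi_model", "proxy_model")`. Its
#'   `params` hold the knots and knot second derivatives; per-interval cubic
#'   coefficients are available via [spline_coefficients()].
#' @examples
#' ts <- trajectory_series(0:4, c(1, 3, 2, 5, 4))
#' m <- fit_csi(ts)
#' predict(m, 2.5)
#' @export
fit_csi <- function(ts) {
  stopifnot(inherits(ts, "trajectory_series"))
  n <- length(ts$x)
  assert_that(n >= 3, "CSI needs at least 3 points (got %d)", n)
  assert_that(!anyDuplicated(ts$x), "duplicate x values")
  x <- ts$x
  y <- ts$y
  h <- diff(x)
  # Tridiagonal system for interior second derivatives M_2..M_{n-1};
  # natural boundary: M_1 = M_n = 0.
  m <- n - 2L
  lower <- h[seq_len(m - 1) + 1]          # sub-diagonal  h_i
  diagm <- 2 * (h[seq_len(m)] + h[seq_len(m) + 1])
  upper <- h[seq_len(m - 1) + 1]          # super-diagonal h_i
  slopes <- diff(y) / h
  rhs <- 6 * diff(slopes)
  M <- c(0, thomas_solve(lower, diagm, upper, rhs), 0)
  structure(list(kind = "CSI", x = x, y = y, m2 = M,
                 domain = range(x), x_axis = ts$x_axis),
            class = c("csi_model", "proxy_model"))
}

# Thomas algorithm for a tridiagonal system; lower/upper have length n-1.
thomas_solve <- function(lower, diagm, upper, rhs) {
  n <- length(diagm)
  if (n == 1L) return(rhs / diagm)
  cp <- numeric(n - 1)
  dp <- numeric(n)
  cp[1] <- upper[1] / diagm[1]
  dp[1] <- rhs[1] / diagm[1]
  for (i in 2:n) {
    denom <- diagm[i] - lower[i - 1] * cp[i - 1]
    if (i < n) cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / denom
  }
  out <- numeric(n)
  out[n] <- dp[n]
  for (i in (n - 1):1) out[i] <- dp[i] - cp[i] * out[i + 1]
  out
}

# Evaluate the natural spline; interval index clamped so queries outside the
# domain extend the end-interval cubics.
csi_eval <- function(model, x) {
  kx <- model$x
  ky <- model$y
  M <- model$m2
  i <- findInterval(x, kx, all.inside = TRUE)
  h <- kx[i + 1] - kx[i]
  a <- (kx[i + 1] - x) / h
  b <- (x - kx[i]) / h
  a * ky[i] + b * ky[i + 1] +
    ((a^3 - a) * M[i] + (b^3 - b) * M[i + 1]) * h^2 / 6
}

#' Per-interval cubic coefficients of a fitted natural spline
#'
#' @param model a `csi_model`.
#' @return `data.frame` with one row per interval: `x_left`, `x_right` and
#'   coefficients `c0..c3` of `sum(ck * (x - x_left)^k)`.
#' @export
spline_coefficients <- function(model) {
  stopifnot(inherits(model, "csi_model"))
  x <- model$x
  y <- model$y
  M <- model$m2
  n <- length(x)
  i <- seq_len(n - 1)
  h <- diff(x)
  data.frame(
    x_left = x[i], x_right = x[i + 1],
    c0 = y[i],
    c1 = diff(y) / h - h * (2 * M[i] + M[i + 1]) / 6,
    c2 = M[i] / 2,
    c3 = (M[i + 1] - M[i]) / (6 * h))
}

#' Second derivative of a fitted natural spline at its knots
#'
#' @param model a `csi_model`.
#' @return numeric vector, one value per knot; the first and last are zero by
#'   the natural boundary condition.
#' @export
csi_second_derivatives <- function(model) {
  stopifnot(inherits(model, "csi_model"))
  model$m2
}
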