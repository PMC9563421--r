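#' A sparse trajectory of ROAV scores
#'
#' Ordered (x, y) observations of one compound's ROAV along hydrolysis time
#' (hours) or along the degree of hydrolysis (percent). All three surrogate
#' models fit these series.
#'
#' @param x strictly increasing abscissa values (length >= 2).
#' @param y ROAV values, same length, finite.
#' @param x_axis `"time"` or `"dh"`.
#' @return an object of class `"trajectory_series"`.
#' @export
trajectory_series <- function(x, y, x_axis = c("time", "dh")) {
  x_axis <- match.arg(x_axis)
  assert_that(is.numeric(x) && is.numeric(y), "x and y must be numeric")
  assert_that(length(x) == length(y), "x and y must have equal length")
  assert_that(length(x) >= 2, "a trajectory needs at least 2 points")
  assert_that(all(is.finite(x)) && all(is.finite(y)),
              "x and y must be finite (no missing values)")
  assert_that(all(diff(x) > 0), "x must be strictly increasing")
  structure(list(x = as.numeric(x), y = as.numeric(y), x_axis = x_axis),
            class = "trajectory_series")
}

#' @export
print.trajectory_series <- function(x, ...) {
  cat(sprintf("<trajectory_series> %d points over %s in [%g, %g]\n",
              length(x$x), x$x_axis, min(x$x), max(x$x)))
  invisible(x)
}
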