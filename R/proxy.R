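#' Fit a surrogate trajectory model by kind
#'
#' Thin dispatcher over [fit_csi()], [fit_pcf()] and [fit_cpm()] sharing a
#' common fit/predict/sample contract.
#'
#' @param ts a [trajectory_series()].
#' @param kind `"CSI"`, `"PCF"` or `"CPM"`.
#' @param ... passed to the kind-specific fitter (`degree` for PCF, `config`
#'   for CPM).
#' @return a fitted `proxy_model`.
#' @export
fit_proxy <- function(ts, kind = c("CSI", "PCF", "CPM"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         CSI = fit_csi(ts, ...),
         PCF = fit_pcf(ts, ...),
         CPM = fit_cpm(ts, ...))
}

#' Predict from a fitted surrogate model
#'
#' Evaluation is analytic for CSI and PCF and deterministic for CPM.
#' Queries outside the fitted domain warn and follow the model's documented
#' extrapolation policy: CSI extends its end-interval cubics, PCF evaluates
#' the polynomial, CPM clamps to the nearest boundary value.
#'
#' @param object a fitted `proxy_model`.
#' @param x numeric vector of abscissa values.
#' @param ... unused.
#' @return numeric vector of predictions, same length as `x`.
#' @export
predict.proxy_model <- function(object, x, ...) {
  assert_that(is.numeric(x) && all(is.finite(x)), "x must be finite numeric")
  out_of <- x < object$domain[1] | x > object$domain[2]
  if (any(out_of)) {
    warning(sprintf("%d point(s) outside fitted domain [%g, %g]: %s",
                    sum(out_of), object$domain[1], object$domain[2],
                    switch(object$kind,
                           CSI = "extending end-interval cubics",
                           PCF = "extending the polynomial",
                           CPM = "clamping to boundary values")),
            call. = FALSE)
  }
  switch(object$kind,
         CSI = csi_eval(object, x),
         PCF = pcf_eval(object, x),
         CPM = cpm_eval(object, pmin(pmax(x, object$domain[1]),
                                     object$domain[2])))
}

#' Sample a fitted curve on an arithmetic progression
#'
#' Evaluates the model on `n` evenly spaced points spanning its fitted
#' domain, endpoints included — the dense grid used both by the CPM and for
#' plotting fitted trajectories.
#'
#' @param model a fitted `proxy_model`.
#' @param n number of points (>= 2); default 100.
#' @return `data.frame` with columns `x` and `y`.
#' @export
sample_curve <- function(model, n = 100L) {
  stopifnot(inherits(model, "proxy_model"))
  assert_that(is_number(n) && n >= 2 && n == round(n),
              "n must be an integer >= 2")
  x <- seq(model$domain[1], model$domain[2], length.out = n)
  data.frame(x = x, y = predict(model, x))
}

#' @export
print.proxy_model <- function(x, ...) {
  extra <- switch(x$kind,
                  CSI = sprintf("%d knots", length(x$x)),
                  PCF = sprintf("degree %d", x$degree),
                  CPM = sprintf("grid %d, smoother %s", x$config$grid_n,
                                x$config$smoother))
  cat(sprintf("<proxy_model:%s> %s, domain [%g, %g] (%s)\n", x$kind, extra,
              x$domain[1], x$domain[2], x$x_axis))
  invisible(x)
}
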