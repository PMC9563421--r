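#' Configuration of the curve prediction model (CPM)
#'
#' The CPM is a two-stage surrogate for sparse trajectories: (i) the training
#' points are densified onto an arithmetic progression of `grid_n` points
#' spanning the training range (both endpoints included) using a
#' shape-preserving piecewise-cubic interpolant that introduces no new
#' extrema; (ii) a smooth regressor is fitted to the densified set. The
#' default smoother is a small single-hidden-layer neural network trained
#' under a fixed seed; a ridge-regularised polynomial is available as a
#' deterministic alternative. Predictions are clamped at zero when `clamp` is
#' set, so non-negative training data yield non-negative curves.
#'
#' @param grid_n densification grid size (>= 2); default 100.
#' @param smoother `"nnet"` (default) or `"ridge"`.
#' @param seed RNG seed for the neural-network weights; the caller's RNG
#'   state is restored after fitting.
#' @param hidden_units hidden-layer width of the network smoother.
#' @param decay weight decay of the network smoother.
#' @param maxit maximum BFGS iterations for network training.
#' @param poly_degree degree of the ridge-polynomial smoother.
#' @param ridge_lambda ridge penalty of the polynomial smoother.
#' @param clamp clamp predictions at zero (default `TRUE`).
#' @return a list of class `"cpm_config"`.
#' @export
cpm_config <- function(grid_n = 100L, smoother = c("nnet", "ridge"),
                       seed = 1L, hidden_units = 8L, decay = 1e-4,
                       maxit = 2000L, poly_degree = 8L, ridge_lambda = 1e-8,
                       clamp = TRUE) {
  smoother <- match.arg(smoother)
  assert_that(is_number(grid_n) && grid_n >= 2 && grid_n == round(grid_n),
              "grid_n must be an integer >= 2")
  assert_that(is_number(seed), "seed must be a number")
  assert_that(is_number(hidden_units) && hidden_units >= 1,
              "hidden_units must be >= 1")
  assert_that(is_number(decay) && decay >= 0, "decay must be >= 0")
  assert_that(is_number(maxit) && maxit >= 1, "maxit must be >= 1")
  assert_that(is_number(poly_degree) && poly_degree >= 1,
              "poly_degree must be >= 1")
  assert_that(is_number(ridge_lambda) && ridge_lambda >= 0,
              "ridge_lambda must be >= 0")
  assert_that(is.logical(clamp) && length(clamp) == 1L && !is.na(clamp),
              "clamp must be TRUE or FALSE")
  structure(list(grid_n = as.integer(grid_n), smoother = smoother,
                 seed = as.integer(seed),
                 hidden_units = as.integer(hidden_units), decay = decay,
                 maxit = as.integer(maxit),
                 poly_degree = as.integer(poly_degree),
                 ridge_lambda = ridge_lambda, clamp = clamp),
            class = "cpm_config")
}

#' Fit the curve prediction model
#'
#' See [cpm_config()] for the two-stage construction. The fit is bitwise
#' deterministic given the same series and configuration, and fitting does
#' not disturb the caller's RNG stream.
#'
#' @param ts a [trajectory_series()] with at least 3 points.
#' @param config a [cpm_config()].
#' @return a fitted model of class `c("cpm_model", "proxy_model")`.
#' @examples
#' ts <- trajectory_series(0:4, c(1, 3, 2, 5, 4))
#' m <- fit_cpm(ts)
#' predict(m, 2.5)
#' @export
fit_cpm <- function(ts, config = cpm_config()) {
  stopifnot(inherits(ts, "trajectory_series"))
  assert_that(inherits(config, "cpm_config"),
              "config must be built by cpm_config()")
  n <- length(ts$x)
  assert_that(n >= 3, "CPM needs at least 3 points (got %d)", n)
  grid <- seq(min(ts$x), max(ts$x), length.out = config$grid_n)
  dense <- stats::splinefun(ts$x, ts$y, method = "monoH.FC")(grid)
  yr <- range(dense)
  model <- list(kind = "CPM", config = config, domain = range(ts$x),
                x = ts$x, y = ts$y, grid = grid, dense = dense,
                y_range = yr, x_axis = ts$x_axis)
  if (diff(yr) < .Machine$double.eps^0.5) {
    model$constant <- dense[1]                 # degenerate flat series
    class(model) <- c("cpm_model", "proxy_model")
    return(model)
  }
  xs <- (grid - model$domain[1]) / diff(model$domain)
  ys <- (dense - yr[1]) / diff(yr)
  if (config$smoother == "nnet") {
    model$fit <- with_seed(config$seed,
      nnet::nnet(x = matrix(xs), y = ys, size = config$hidden_units,
                 linout = TRUE, decay = config$decay, maxit = config$maxit,
                 trace = FALSE))
  } else {
    V <- outer(xs, 0:config$poly_degree, `^`)
    model$ridge_coef <- as.numeric(
      solve(crossprod(V) + config$ridge_lambda * diag(config$poly_degree + 1),
            crossprod(V, ys)))
  }
  class(model) <- c("cpm_model", "proxy_model")
  model
}

cpm_eval <- function(model, x) {
  if (!is.null(model$constant)) return(rep(model$constant, length(x)))
  xs <- (x - model$domain[1]) / diff(model$domain)
  ys <- if (model$config$smoother == "nnet") {
    as.numeric(stats::predict(model$fit, matrix(xs)))
  } else {
    b <- model$ridge_coef
    out <- rep(b[length(b)], length(xs))
    for (k in rev(seq_len(length(b) - 1))) out <- out * xs + b[k]
    out
  }
  out <- ys * diff(model$y_range) + model$y_range[1]
  if (model$config$clamp) out <- pmax(out, 0)
  out
}
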