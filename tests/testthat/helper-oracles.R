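# Independent oracles and tiny builders shared across test files.

# Natural cubic spline by dense solve of the defining linear system:
# second derivatives M satisfy M_1 = M_n = 0 and, at interior knots,
# h_{i-1} M_{i-1} + 2(h_{i-1}+h_i) M_i + h_i M_{i+1} = 6 (d_i - d_{i-1})
# with d_i the interval slopes. Evaluation uses the textbook segment form.
# Kept free of package internals so it can check them.
dense_natural_spline <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 1
  A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  M <- solve(A, b)
  eval_at <- function(q) {
    i <- findInterval(q, x, all.inside = TRUE)
    hh <- x[i + 1] - x[i]
    a <- (x[i + 1] - q) / hh
    bb <- (q - x[i]) / hh
    a * y[i] + bb * y[i + 1] +
      ((a^3 - a) * M[i] + (bb^3 - bb) * M[i + 1]) * hh^2 / 6
  }
  list(M = M, eval = eval_at)
}

# A 2-sample x 3-compound content matrix with simple round numbers.
tiny_content <- function() {
  v <- matrix(c(2, 1, 0.5,
                4, 0, 0.25), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("alpha", "beta", "gamma")))
  content_matrix(v)
}

tiny_thresholds <- function() {
  c(alpha = 0.001, beta = 0.01, gamma = 0.1)
}

random_trajectory <- function(n, span = 8) {
  x <- sort(runif(n, 0, span))
  while (any(diff(x) < 1e-3)) x <- sort(runif(n, 0, span))
  trajectory_series(x, runif(n, 0, 5))
}
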