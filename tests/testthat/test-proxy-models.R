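test_that("natural spline equals the dense-matrix solve of its defining system", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    ts <- random_trajectory(n)
    m <- fit_csi(ts)
    oracle <- dense_natural_spline(ts$x, ts$y)
    expect_equal(csi_second_derivatives(m), oracle$M, tolerance = 1e-9)
    q <- runif(20, min(ts$x), max(ts$x))
    expect_equal(predict(m, q), oracle$eval(q), tolerance = 1e-9)
    # cross-check against the reference natural-spline implementation
    expect_equal(predict(m, q),
                 stats::splinefun(ts$x, ts$y, method = "natural")(q),
                 tolerance = 1e-9)
  }
})

test_that("natural spline interpolates its knots with zero end curvature", {
  ts <- trajectory_series(c(0, 2, 4, 6, 8), c(3.48, 6.801, 3.929, 5.023, 6.876))
  m <- fit_csi(ts)
  expect_equal(predict(m, ts$x), ts$y, tolerance = 1e-12)
  m2 <- csi_second_derivatives(m)
  expect_equal(m2[1], 0)
  expect_equal(m2[length(m2)], 0)
  # frozen oracle value: dense solve evaluated midway between two knots
  expect_equal(predict(m, 5), 3.976982, tolerance = 1e-6)
  coefs <- spline_coefficients(m)
  expect_equal(nrow(coefs), 4)
  # coefficients reconstruct the same curve
  i <- 3
  xq <- 4.7
  expect_equal(sum(coefs[i, c("c0", "c1", "c2", "c3")] *
                     (xq - coefs$x_left[i])^(0:3)),
               predict(m, xq), tolerance = 1e-12)
})

test_that("a spline through collinear points is that line everywhere", {
  ts <- trajectory_series(c(0, 1, 3, 7), 2 + 0.5 * c(0, 1, 3, 7))
  m <- fit_csi(ts)
  q <- seq(0, 7, length.out = 50)
  expect_equal(predict(m, q), 2 + 0.5 * q, tolerance = 1e-10)
  expect_equal(max(abs(csi_second_derivatives(m))), 0, tolerance = 1e-10)
})

test_that("spline fitting refuses degenerate inputs", {
  expect_error(fit_csi(trajectory_series(c(0, 1), c(1, 2))), "at least 3")
  expect_error(trajectory_series(c(0, 1, 1), c(1, 2, 3)), "increasing")
  expect_error(trajectory_series(c(0, 1, 2), c(1, NA, 3)), "finite")
})

test_that("polynomial fit solves the normal equations", {
  ts <- trajectory_series(c(0, 2, 4, 6, 8), c(3.48, 6.801, 3.929, 5.023, 6.876))
  m <- fit_pcf(ts, degree = 3)
  V <- outer(ts$x, 0:3, `^`)
  # residuals orthogonal to every monomial basis column (normal equations)
  expect_equal(as.numeric(crossprod(V, m$residuals)), rep(0, 4),
               tolerance = 1e-9)
  expect_equal(sum(m$residuals), 0, tolerance = 1e-9)
  # matches the standard least-squares machinery
  expect_equal(unname(m$coefficients),
               unname(coef(lm(y ~ poly(x, 3, raw = TRUE),
                              data.frame(x = ts$x, y = ts$y)))),
               tolerance = 1e-9)

  # local optimality: no perturbed coefficient vector does better
  rss <- sum(m$residuals^2)
  set.seed(7)
  for (i in 1:50) {
    b <- m$coefficients + rnorm(4, 0, 0.01)
    expect_gte(sum((ts$y - as.numeric(V %*% b))^2), rss)
  }
})

test_that("polynomial degree bounds follow the data size", {
  ts <- trajectory_series(c(0, 2, 4, 6, 8), c(1, 5, 2, 4, 3))
  interp <- fit_pcf(ts, degree = 4)
  expect_equal(predict(interp, ts$x), ts$y, tolerance = 1e-9)
  expect_error(fit_pcf(ts, degree = 5), "underdetermined")
  expect_error(fit_pcf(ts, degree = 0), "positive integer")
  line <- fit_pcf(trajectory_series(0:2, c(0, 1, 2)), degree = 1)
  expect_equal(predict(line, 1.5), 1.5, tolerance = 1e-12)
  expect_equal(max(abs(line$residuals)), 0, tolerance = 1e-12)
})

test_that("CPM is deterministic, non-negative, and leaves the RNG alone", {
  ts <- trajectory_series(c(0, 2, 4, 6, 8), c(3.285, 11.567, 2.277, 1.807, 0.686))
  m1 <- fit_cpm(ts)
  m2 <- fit_cpm(ts)
  q <- seq(0, 8, length.out = 41)
  expect_identical(predict(m1, q), predict(m2, q))
  expect_true(all(predict(m1, q) >= 0))
  expect_true(all(sample_curve(m1, 200)$y >= 0))

  # fitting must not advance or reset the caller's RNG stream
  set.seed(123)
  a <- runif(2)
  set.seed(123)
  b1 <- runif(1)
  invisible(fit_cpm(ts))
  b2 <- runif(1)
  expect_identical(c(b1, b2), a)

  # different seeds give different (but valid) network fits
  m3 <- fit_cpm(ts, cpm_config(seed = 99))
  expect_false(identical(predict(m1, q), predict(m3, q)))
})

test_that("CPM reproduces flat series exactly and validates its config", {
  ts <- trajectory_series(c(0, 2, 4, 6, 8), rep(2.5, 5))
  m <- fit_cpm(ts)
  expect_equal(predict(m, seq(0, 8, 0.5)), rep(2.5, 17),
               tolerance = 1e-3 * 2.5)
  expect_error(cpm_config(grid_n = 1), "grid_n")
  expect_error(cpm_config(smoother = "loess"), "arg")
  expect_error(cpm_config(decay = -1), "decay")
  expect_error(fit_cpm(trajectory_series(0:1, c(1, 2))), "at least 3")
  expect_error(fit_cpm(ts, config = list(grid_n = 100)), "cpm_config")
})

test_that("the ridge smoother variant tracks the densified curve", {
  ts <- trajectory_series(c(0, 2, 4, 6, 8), c(1.359, 3.286, 2.11, 1.475, 2.013))
  m <- fit_cpm(ts, cpm_config(smoother = "ridge"))
  dense <- stats::splinefun(ts$x, ts$y, method = "monoH.FC")
  q <- seq(0, 8, length.out = 81)
  expect_lt(max(abs(predict(m, q) - pmax(dense(q), 0))), 0.1)
})

test_that("prediction contracts: vectorization, knots, extrapolation", {
  ts <- trajectory_series(c(0, 2, 4, 6, 8), c(1, 4, 2, 5, 3))
  for (kind in c("CSI", "PCF", "CPM")) {
    m <- fit_proxy(ts, kind)
    q <- c(0.5, 3.3, 7.9)
    expect_equal(predict(m, q), vapply(q, function(z) predict(m, z),
                                       numeric(1)))
    expect_warning(predict(m, 9), "outside fitted domain")
  }
  mcsi <- fit_proxy(ts, "CSI")
  expect_equal(predict(mcsi, ts$x), ts$y, tolerance = 1e-12)
  # CSI extrapolates its end cubic; CPM clamps to the boundary value
  co <- spline_coefficients(mcsi)
  last <- nrow(co)
  expect_equal(suppressWarnings(predict(mcsi, 9)),
               sum(co[last, c("c0", "c1", "c2", "c3")] *
                     (9 - co$x_left[last])^(0:3)),
               tolerance = 1e-12)
  mcpm <- fit_proxy(ts, "CPM")
  expect_equal(suppressWarnings(predict(mcpm, 100)), predict(mcpm, 8))
})

test_that("sampled curves are arithmetic progressions over the domain", {
  ts <- trajectory_series(c(0, 2, 4, 6, 8), c(1, 4, 2, 5, 3))
  m <- fit_csi(ts)
  two <- sample_curve(m, 2)
  expect_equal(two$x, c(0, 8))
  g <- sample_curve(m, 100)
  expect_equal(diff(g$x), rep(8 / 99, 99), tolerance = 1e-12)
  # knots lying on the grid are reproduced exactly
  g5 <- sample_curve(m, 5)
  expect_equal(g5$x, ts$x)
  expect_equal(g5$y, ts$y, tolerance = 1e-12)
  expect_error(sample_curve(m, 1), ">= 2")
})

test_that("spline oscillation on clustered abscissae exceeds the CPM's", {
  # sampling at the measured DH spacing clusters three points at the high
  # end; the natural spline then swings far beyond the data while the
  # shape-preserving CPM stays near it
  dhx <- c(0, 9.40, 11.93, 14.32, 14.77)
  set.seed(11)
  worse <- 0
  for (i in 1:20) {
    y <- runif(5, 0.5, 5)
    ts <- trajectory_series(dhx, y)
    g <- seq(0, 14.77, length.out = 300)
    mx_csi <- max(abs(predict(fit_csi(ts), g)))
    mx_cpm <- max(abs(predict(fit_cpm(ts), g)))
    worse <- worse + (mx_csi > mx_cpm)
  }
  expect_gte(worse, 17)
})
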