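# Cubic splines: boundary conditions, interpolation, derivatives

test_that("linear data give a spline with zero curvature reproducing the line", {
  for (bnd in c("natural", "parabolic", "cubic_runout")) {
    ts <- line_series(c(0, 0.7, 1.1, 3), intercept = 1, slope = 2)
    sp <- fit_spline(ts, boundary = bnd)
    expect_equal(max(abs(sp$moments)), 0, tolerance = 1e-12)
    g <- seq(0, 3, length.out = 37)
    expect_equal(unname(eval_trajectory(sp, g)[, 1]), 1 + 2 * g,
                 tolerance = 1e-12)
    expect_equal(max(abs(eval_trajectory(sp, g, order = 2))), 0,
                 tolerance = 1e-12)
  }
})

test_that("boundary conditions hold at the end knots", {
  ts <- timeseries(0:5, rbind(sin(0:5)))
  sp_nat <- fit_spline(ts, "natural")
  expect_equal(sp_nat$moments[1, 1], 0)
  expect_equal(sp_nat$moments[6, 1], 0)
  expect_equal(unname(eval_trajectory(sp_nat, 0, order = 2)), 0,
               tolerance = 1e-12)
  sp_par <- fit_spline(ts, "parabolic")
  expect_equal(sp_par$moments[1, 1], sp_par$moments[2, 1])
  expect_equal(sp_par$moments[5, 1], sp_par$moments[6, 1])
  sp_run <- fit_spline(ts, "cubic_runout")
  expect_equal(sp_run$moments[1, 1],
               2 * sp_run$moments[2, 1] - sp_run$moments[3, 1])
  expect_equal(sp_run$moments[6, 1],
               2 * sp_run$moments[5, 1] - sp_run$moments[4, 1])
})

test_that("spline matches the dense tridiagonal moment-system oracle to 1e-12", {
  x <- as.numeric(0:3)
  y <- sin(x)
  g <- seq(0, 3, length.out = 201)
  for (bnd in c("natural", "parabolic", "cubic_runout")) {
    sp <- fit_spline(timeseries(x, rbind(y)), boundary = bnd)
    orc <- oracle_spline(x, y, boundary = bnd)
    for (ord in 0:2)
      expect_lt(max(abs(eval_trajectory(sp, g, ord)[, 1] - orc(g, ord))),
                1e-12)
  }
  # second independent oracle for the default boundary
  sf <- stats::splinefun(x, y, method = "natural")
  sp <- fit_spline(timeseries(x, rbind(y)))
  expect_lt(max(abs(eval_trajectory(sp, g)[, 1] - sf(g))), 1e-12)
})

test_that("evaluation at knots returns the data exactly", {
  set.seed(42)
  x <- cumsum(runif(8, 0.2, 1.5))
  y <- matrix(rnorm(16), nrow = 2)
  sp <- fit_spline(timeseries(x, y))
  # exact up to round-off (the last knot is reconstructed from interval
  # coefficients, so a few ulps of noise are expected there)
  expect_equal(unname(t(eval_trajectory(sp, x))), unname(y),
               tolerance = 1e-14)
})

test_that("first derivative agrees with a central finite difference", {
  x <- seq(0, 3, length.out = 7)
  sp <- fit_spline(timeseries(x, rbind(exp(-x))))
  tt <- seq(0.2, 2.8, length.out = 11)
  h <- 1e-6
  fd <- (eval_trajectory(sp, tt + h) - eval_trajectory(sp, tt - h)) / (2 * h)
  d1 <- eval_trajectory(sp, tt, order = 1)
  expect_lt(max(abs(d1 - fd)) / max(abs(d1)), 1e-5)
})

test_that("second derivative is continuous across interior knots", {
  set.seed(7)
  x <- seq(0, 4, by = 0.5)
  sp <- fit_spline(timeseries(x, rbind(rnorm(9))))
  eps <- 1e-9
  for (k in x[c(-1, -length(x))]) {
    left <- eval_trajectory(sp, k - eps, order = 2)
    right <- eval_trajectory(sp, k + eps, order = 2)
    expect_lt(abs(left - right), 1e-6)  # |S''' | * 2eps plus round-off
  }
})

test_that("interpolation error decays at 4th order under knot doubling", {
  err <- vapply(c(8, 16, 32), function(n) {
    x <- seq(0, 3, length.out = n + 1)
    sp <- fit_spline(timeseries(x, rbind(exp(-x))))
    # measure away from the natural-boundary layers
    g <- seq(0.75, 2.25, length.out = 401)
    max(abs(eval_trajectory(sp, g)[, 1] - exp(-g)))
  }, numeric(1))
  ratios <- err[-3] / err[-1]
  # >= 4th order per doubling; measured away from the natural-boundary
  # layers, where decay can exceed the asymptotic 16x (globally the layers
  # cap a natural spline of exp(-t) at 2nd order, since f'' != 0 there)
  expect_true(all(ratios > 8))
})

test_that("cubic polynomials are reproduced by the cubic-runout spline", {
  f <- function(t) 1 - 2 * t + 0.5 * t^2 + 0.25 * t^3
  x <- seq(0, 4, by = 0.8)
  sp <- fit_spline(timeseries(x, rbind(f(x))), boundary = "cubic_runout")
  g <- seq(0, 4, length.out = 101)
  expect_lt(max(abs(eval_trajectory(sp, g)[, 1] - f(g))), 1e-10)
  # the natural spline agrees away from its boundary layers
  spn <- fit_spline(timeseries(seq(0, 4, by = 0.25), rbind(f(seq(0, 4, by = 0.25)))))
  gi <- seq(1.5, 2.5, length.out = 51)
  expect_lt(max(abs(eval_trajectory(spn, gi)[, 1] - f(gi))), 2e-3)
})

test_that("sized-input and extrapolation errors are raised", {
  expect_error(fit_spline(timeseries(c(0, 1), rbind(c(1, 2)))),
               "at least 3", class = "odeinfer_size_error")
  expect_error(fit_spline(timeseries(0:2, rbind(0:2)), "cubic_runout"),
               "at least 4", class = "odeinfer_size_error")
  # duplicate knots cannot pass the timeseries constructor ...
  expect_error(timeseries(c(0, 1, 1, 2), rbind(1:4)),
               class = "odeinfer_validation_error")
  # ... and are caught again if a malformed object is forced through
  bad <- structure(list(times = c(0, 1, 1, 2),
                        values = rbind(1:4), component_names = "X"),
                   class = "timeseries")
  expect_error(fit_spline(bad), class = "odeinfer_validation_error")
  sp <- fit_spline(timeseries(0:3, rbind(0:3)))
  expect_error(eval_trajectory(sp, 3.5),
               class = "odeinfer_extrapolation_error")
  expect_error(eval_trajectory(sp, -0.1),
               class = "odeinfer_extrapolation_error")
})

test_that("components are splined independently on the shared grid", {
  x <- 0:4
  y <- rbind(sin(x), cos(x))
  sp <- fit_spline(timeseries(x, y))
  sp1 <- fit_spline(timeseries(x, y[1, , drop = FALSE]))
  g <- seq(0, 4, length.out = 31)
  expect_equal(eval_trajectory(sp, g)[, 1], eval_trajectory(sp1, g)[, 1])
})
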