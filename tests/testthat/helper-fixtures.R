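# Small models and datasets shared across test files.  Everything is built
# in code; nothing is read from disk.

# one-parameter exponential decay, used for GA recovery tests
decay_model <- function(wmax = 2) {
  ode_model("decay", "X", "theta",
            function(state, params, t) -params[1] * state[1],
            initial_state = 2, wmax = wmax, exact_params = 0.5)
}

# rhs identically zero: trajectories are constant
zero_model <- function(n = 2) {
  ode_model("still", paste0("X", seq_len(n)), "theta",
            function(state, params, t) rep(0, n),
            initial_state = seq_len(n), wmax = 1, exact_params = 1)
}

# finite-time blow-up: dX/dt = theta * X^2 from X = 1 explodes at t = 1/theta
blowup_model <- function() {
  ode_model("blowup", "X", "theta",
            function(state, params, t) params[1] * state[1]^2,
            initial_state = 1, wmax = 2, exact_params = 0.4)
}

g1s_dataset <- function(...) make_standard_dataset(g1s_model(), ...)
erk_dataset <- function(...) make_standard_dataset(erk_model(), ...)

# timeseries lying exactly on a line y = a + b t
line_series <- function(times, intercept = 1, slope = 2, ncomp = 1) {
  vals <- matrix(rep(intercept + slope * times, each = ncomp), nrow = ncomp)
  timeseries(times, vals)
}

# independent oracle: solve the natural/parabolic/runout moment system with
# a dense base-R solve() and evaluate the spline directly
oracle_spline <- function(x, y, boundary = "natural") {
  m <- length(x)
  h <- diff(x)
  A <- matrix(0, m, m)
  rhs <- numeric(m)
  for (i in 2:(m - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  if (boundary == "natural") {
    A[1, 1] <- 1; A[m, m] <- 1
  } else if (boundary == "parabolic") {
    A[1, 1] <- 1; A[1, 2] <- -1
    A[m, m] <- 1; A[m, m - 1] <- -1
  } else {
    A[1, 1] <- 1; A[1, 2] <- -2; A[1, 3] <- 1
    A[m, m] <- 1; A[m, m - 1] <- -2; A[m, m - 2] <- 1
  }
  M <- solve(A, rhs)
  function(t, order = 0) {
    i <- pmin(pmax(findInterval(t, x), 1L), m - 1L)
    hh <- h[i]
    a <- y[i]
    b <- (y[i + 1] - y[i]) / hh - hh * (2 * M[i] + M[i + 1]) / 6
    cc <- M[i] / 2
    d <- (M[i + 1] - M[i]) / (6 * hh)
    u <- t - x[i]
    if (order == 0) a + u * (b + u * (cc + u * d))
    else if (order == 1) b + u * (2 * cc + 3 * d * u)
    else 2 * cc + 6 * d * u
  }
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected), 1e-300), tol)
}
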