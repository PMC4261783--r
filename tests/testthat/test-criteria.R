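# The sixteen fitness criteria and their building blocks

test_that("criterion table matches the published compositions", {
  expect_length(criterion_ids(), 16L)
  expect_equal(criterion_spec("DAE3")$components, c(2L, 4L, 6L))
  expect_equal(criterion_spec("CAE3")$components, c(10L, 12L, 14L))
  expect_equal(criterion_spec("CAE4")$components, c(10L, 12L, 16L))
  expect_equal(criterion_spec("DRE4")$components, c(3L, 5L, 9L))
  expect_equal(criterion_spec("CRE2")$mode, "continuous")
  expect_equal(criterion_spec("DAE2")$error_kind, "absolute")
  expect_error(criterion_spec("XAE1"), class = "odeinfer_validation_error")
  expect_error(criterion_spec("CAE1", weights = c(1, 2)),
               class = "odeinfer_validation_error")
})

test_that("discrete value errors match hand computation", {
  obs <- timeseries(c(0, 1), rbind(c(1, 2)))
  sim <- timeseries(c(0, 1), rbind(c(1.5, 2)))
  expect_equal(discrete_value_error(sim, obs, "absolute"), 0.25)
  expect_equal(discrete_value_error(sim, obs, "relative"), 0.25)
  expect_equal(discrete_value_error(obs, obs, "absolute"), 0)
  expect_equal(discrete_value_error(obs, obs, "relative"), 0)
  # grid mismatch is a validation error
  sim2 <- timeseries(c(0, 2), rbind(c(1.5, 2)))
  expect_error(discrete_value_error(sim2, obs),
               class = "odeinfer_validation_error")
})

test_that("discrete derivative errors follow the spline-slope reading", {
  knots <- as.numeric(0:3)
  obs <- line_series(knots, 0, 1)   # y = t   -> slope 1, curvature 0
  sim <- line_series(knots, 0, 2)   # y = 2t  -> slope 2, curvature 0
  expect_equal(discrete_derivative_error(sim, obs, 1, "absolute"), 4)
  expect_equal(discrete_derivative_error(sim, obs, 2, "absolute"), 0)
  expect_equal(discrete_derivative_error(obs, obs, 1, "relative"), 0)
})

test_that("division guards identify zero observations and can exclude them", {
  obs <- timeseries(c(0, 1, 2), rbind(c(0, 1, 2)))
  sim <- timeseries(c(0, 1, 2), rbind(c(0.5, 1, 2)))
  expect_error(discrete_value_error(sim, obs, "relative"),
               class = "odeinfer_guard_error")
  expect_equal(discrete_value_error(sim, obs, "relative",
                                    zero_policy = "exclude"), 0)
  # relative slope error against constant observations (slope identically 0)
  cobs <- timeseries(c(0, 1, 2), rbind(c(1, 1, 1)))
  expect_error(discrete_derivative_error(sim, cobs, 1, "relative"),
               class = "odeinfer_guard_error")
})

test_that("roughness penalty is a simulation-only diagnostic", {
  straight <- line_series(as.numeric(0:4), 2, 3)
  expect_equal(roughness_penalty(straight), 0)
  curved <- timeseries(as.numeric(0:4), rbind(c(0, 1, 0, 1, 0)))
  p <- roughness_penalty(curved, mode = "continuous", n_panels = 200)
  # brute-force sampled maximum over a very dense grid
  traj <- fit_spline(curved)
  dense <- seq(0, 4, length.out = 1e5 + 1)
  brute <- max(abs(eval_trajectory(traj, dense, order = 2)))
  expect_equal(p, brute, tolerance = 1e-4)
  # the sampled-maximum rule: exact equality on its own grid
  g <- seq(0, 4, length.out = 201)
  expect_equal(p, max(abs(eval_trajectory(traj, g, order = 2))))
  expect_gt(p, 0)
})

test_that("composite Simpson integrates cubics exactly and validates panels", {
  expect_identical(simpson_integral(function(t) t^3, 0, 1, 2), 0.25)
  expect_equal(simpson_integral(function(t) 2 + t - t^2 + 3 * t^3, -1, 2, 6),
               integrate(function(t) 2 + t - t^2 + 3 * t^3, -1, 2)$value)
  expect_error(simpson_integral(function(t) t, 0, 1, 3),
               class = "odeinfer_validation_error")
  expect_error(continuous_error(fit_spline(line_series(0:3 + 0.0)),
                                fit_spline(line_series(0:3 + 0.0)),
                                n_panels = 5),
               class = "odeinfer_validation_error")
})

test_that("continuous errors match analytic integrals on constant data", {
  obs <- fit_spline(timeseries(c(0, 1, 2), rbind(c(1, 1, 1))))
  sim <- fit_spline(timeseries(c(0, 1, 2), rbind(c(1.5, 1.5, 1.5))))
  expect_equal(continuous_error(sim, obs, 0, "absolute"), 0.5)
  expect_equal(continuous_error(sim, obs, 0, "relative"), 0.5 / 1^2)
  expect_equal(continuous_error(sim, obs, 1, "absolute"), 0)
  expect_equal(continuous_error(obs, obs, 0, "absolute"), 0)
})

test_that("all sixteen criteria are zero at identity and nonnegative elsewhere", {
  ds <- g1s_dataset()
  obs <- ds$observations
  set.seed(31)
  noisy <- timeseries(obs$times,
                      obs$values * (1 + 0.2 * matrix(rnorm(length(obs$values)),
                                                     nrow(obs$values))))
  for (id in criterion_ids()) {
    spec <- criterion_spec(id)
    expect_identical(evaluate_criterion(spec, obs, obs,
                                        settings = list(quiet = TRUE))$total, 0)
    fv <- evaluate_criterion(spec, noisy, obs, settings = list(quiet = TRUE))
    expect_gte(fv$total, 0)
    expect_equal(fv$total, sum(spec$weights * fv$per_term))
    expect_length(fv$per_term, length(spec$components))
  }
})

test_that("scaling up the residual never decreases an absolute criterion", {
  ds <- g1s_dataset()
  obs <- ds$observations
  set.seed(99)
  resid <- matrix(rnorm(length(obs$values), sd = 0.3), nrow(obs$values))
  vals <- function(lambda, id)
    evaluate_criterion(criterion_spec(id),
                       timeseries(obs$times, obs$values + lambda * resid),
                       obs, settings = list(quiet = TRUE))$total
  for (id in c(paste0("DAE", 1:4), paste0("CAE", 1:4))) {
    v <- vapply(c(0, 0.5, 1, 2, 4), vals, numeric(1), id = id)
    expect_true(all(diff(v) >= 0), info = id)
  }
})

test_that("Simpson panel counts 200 and 400 agree on benchmark trajectories", {
  ds <- g1s_dataset()
  obs_traj <- fit_spline(ds$observations)
  sim <- simulate_model(g1s_model(), g1s_model()$exact_params * 1.2,
                        ds$measurement_times)
  sim_traj <- fit_spline(sim)
  for (ord in 0:2) {
    a <- continuous_error(sim_traj, obs_traj, ord, n_panels = 200)
    b <- continuous_error(sim_traj, obs_traj, ord, n_panels = 400)
    expect_lt(abs(a - b) / b, if (ord == 0) 1e-8 else 1e-6)
  }
})

test_that("discrete and continuous value criteria converge as knots densify", {
  # on a smooth signal, h-weighted DAE1 approaches CAE1
  g1s <- g1s_model()
  ratio <- vapply(c(8, 16, 32), function(N) {
    tt <- seq(50, 300, length.out = N + 1)
    obs <- simulate_model(g1s, times = tt, rtol = 1e-9, atol = 1e-12)
    sim <- simulate_model(g1s, g1s$exact_params * 1.1, tt)
    h <- diff(tt)[1]
    dae <- evaluate_criterion(criterion_spec("DAE1"), sim, obs)$total * h
    cae <- evaluate_criterion(criterion_spec("CAE1"), sim, obs)$total
    dae / cae
  }, numeric(1))
  expect_true(abs(ratio[3] - 1) < abs(ratio[1] - 1))
  expect_lt(abs(ratio[3] - 1), 0.1)
})

test_that("compiled fitness path agrees with the reference R implementation", {
  for (mk in list(g1s_model, erk_model)) {
    model <- mk()
    ds <- make_standard_dataset(model)
    set.seed(17)
    for (id in c("DAE1", "DRE3", "DAE4", "CAE2", "CRE4", "CAE4")) {
      spec <- criterion_spec(id)
      objC <- odeinfer:::make_objective(model, ds$observations, spec,
                                        list(), fast = TRUE)
      objR <- odeinfer:::make_objective(model, ds$observations, spec,
                                        list(), fast = FALSE)
      theta <- model$exact_params * exp(rnorm(length(model$exact_params),
                                              sd = 0.2))
      a <- objC(theta); b <- objR(theta)
      expect_lt(abs(a - b) / max(abs(b), 1e-12), 1e-9)
    }
  }
})

test_that("a failed simulation evaluates to worst fitness, not an error", {
  bm <- blowup_model()
  obs <- simulate_model(bm, 0.4, times = seq(0, 2, by = 0.5))
  fail <- simulate_model(bm, 1.9, times = seq(0, 2, by = 0.5),
                         max_steps = 2000)
  expect_true(is_sim_failure(fail))
  fv <- evaluate_criterion(criterion_spec("CAE2"), fail, obs)
  expect_true(fv$failed)
  expect_identical(fv$total, Inf)
})
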