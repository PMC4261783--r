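#' Generate a standard (synthetic observation) dataset
#'
#' The benchmark protocol replaces experimental data by a "standard
#' simulation": the model is integrated at its reference parameters from
#' the default initial state with tight tolerances and sampled at the
#' measurement time points.  No measurement noise is added by default (the
#' inference protocol assumes noise-free observations); a Gaussian hook is
#' available for extension studies.  Generation is deterministic, so
#' identical settings reproduce bit-identical datasets.
#'
#' @param model an [ode_model()] with `exact_params`.
#' @param times measurement time points; defaults to the model's bundled
#'   recipe (G1/S: `t = 0, 50, ..., 300`; ERK: 7 uniform points on the
#'   bundled window, a documented stand-in).
#' @param rtol,atol solver tolerances (tight by default).
#' @param noise_sd optional Gaussian noise SD (0 = off).
#' @param seed seed used only when `noise_sd > 0`.
#' @return A `benchmark_dataset`: `model_name`, `measurement_times`,
#'   `observations` ([timeseries()]), `exact_params`, `provenance`.
#' @export
#' @examples
#' ds <- make_standard_dataset(g1s_model())
#' ds$observations$times
make_standard_dataset <- function(model, times = NULL, rtol = 1e-8,
                                  atol = 1e-10, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "ode_model"))
  if (is.null(model$exact_params))
    abort_validation("model has no exact_params; cannot generate a standard dataset")
  times <- times %||% default_measurement_times(model$name)
  sim <- simulate_model(model, model$exact_params, times,
                        rtol = rtol, atol = atol)
  if (is_sim_failure(sim))
    abort_odeinfer(paste("standard simulation failed:", sim$message),
                   "odeinfer_simulation_error")
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sim$values <- sim$values +
      matrix(rnorm(length(sim$values), sd = noise_sd), nrow(sim$values))
  }
  structure(list(model_name = model$name,
                 measurement_times = as.numeric(times),
                 observations = sim,
                 exact_params = model$exact_params,
                 provenance = list(solver = "rosenbrock", rtol = rtol,
                                   atol = atol, noise_sd = noise_sd,
                                   seed = seed)),
            class = "benchmark_dataset")
}

default_measurement_times <- function(model_name) {
  switch(model_name,
         g1s = seq(0, 300, by = 50),
         erk = seq(0, 120, length.out = 7L),
         abort_validation(sprintf(
           "no default measurement grid for model '%s'; supply 'times'",
           model_name)))
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf("<benchmark_dataset> %s at %d time points on [%g, %g]\n",
              x$model_name, length(x$measurement_times),
              min(x$measurement_times), max(x$measurement_times)))
  invisible(x)
}

#' Catalogue of bundled benchmark recipes
#'
#' @return Named list with one recipe per bundled benchmark, giving the
#'   model name, default measurement grid, search bound `wmax`,
#'   perturbation strength `mu` for robustness analysis, and the initial
#'   state.
#' @export
list_benchmarks <- function() {
  list(
    erk = list(model = "erk",
               measurement_times = default_measurement_times("erk"),
               wmax = 300, mu = 0.2,
               initial_state = erk_model()$initial_state,
               n_params = 6L),
    g1s = list(model = "g1s",
               measurement_times = default_measurement_times("g1s"),
               wmax = 5, mu = 0.2,
               initial_state = g1s_model()$initial_state,
               n_params = 10L))
}
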