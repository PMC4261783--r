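#' Simulate an ODE model at given time points
#'
#' Integrates the model from its (default or overridden) initial state and
#' returns the trajectory sampled exactly at `times`.  The default solver is
#' a stiff-capable implicit Rosenbrock 2(3) pair (the `ode23s`/`ode23tb`
#' family) because the bundled ERK module is stiff at its reference rates;
#' an independent explicit Dormand-Prince 5(4) pair is available as
#' `solver = "rk45"` and serves as a high-accuracy cross-check.
#'
#' Numerical failure (stiffness blow-up, NaN/Inf states, step-count
#' exhaustion) is never an R error: it yields a `sim_failure` object
#' carrying the offending parameter vector, which the genetic algorithm
#' treats as worst-possible fitness.
#'
#' @param model an [ode_model()].
#' @param params parameter vector (defaults to the model's reference
#'   parameters when present).
#' @param times strictly increasing sampling times; the first entry is the
#'   initial time.
#' @param initial_state optional override of the model's initial state.
#' @param solver `"rosenbrock"` (stiff, default) or `"rk45"` (explicit).
#' @param rtol,atol relative/absolute local error tolerances.
#' @param max_steps cap on accepted + rejected integrator steps.
#'
#' @return A [timeseries()] on success, otherwise a `sim_failure` object
#'   (test with [is_sim_failure()]).
#' @export
#' @examples
#' sim <- simulate_model(g1s_model(), times = seq(0, 300, by = 50))
#' sim$values[, 1]  # the initial state [1, 5]
simulate_model <- function(model, params = model$exact_params, times,
                           initial_state = model$initial_state,
                           solver = c("rosenbrock", "rk45"),
                           rtol = 1e-6, atol = 1e-9, max_steps = 500000L) {
  stopifnot(inherits(model, "ode_model"))
  solver <- match.arg(solver)
  if (is.null(params))
    abort_validation("no 'params' given and the model has no exact_params")
  if (length(params) != length(model$param_names))
    abort_validation(sprintf("expected %d parameters, got %d",
                             length(model$param_names), length(params)))
  if (!is.numeric(times) || length(times) < 1L)
    abort_validation("'times' must be a non-empty numeric vector")
  if (length(times) > 1L && any(diff(times) <= 0))
    abort_validation("'times' must be strictly increasing")
  if (length(initial_state) != length(model$state_names))
    abort_validation("'initial_state' has the wrong length")
  check_number(rtol, "rtol", lower = 1e-14)
  check_number(atol, "atol", lower = 0)

  method <- if (solver == "rk45") 2L else 1L
  res <- integrate_ode_cpp(model$native_id, model$rhs, as.numeric(params),
                           as.numeric(initial_state), as.numeric(times),
                           rtol, atol, method, as.integer(max_steps))
  if (!res$success)
    return(sim_failure(params, res$message, model$name))
  vals <- res$values
  if (any(!is.finite(vals)))
    return(sim_failure(params, "non-finite state in output", model$name))
  timeseries(times, vals, component_names = model$state_names)
}

sim_failure <- function(params, message, model_name) {
  structure(list(params = params, message = message, model = model_name),
            class = "sim_failure")
}

#' @rdname simulate_model
#' @param x object to test.
#' @export
is_sim_failure <- function(x) inherits(x, "sim_failure")

#' @export
print.sim_failure <- function(x, ...) {
  cat(sprintf("<sim_failure> model %s: %s\n", x$model, x$message))
  invisible(x)
}
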