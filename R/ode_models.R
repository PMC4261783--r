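#' Define an ODE model for parameter inference
#'
#' An `ode_model` bundles a dynamical system dX/dt = f(X, theta) with the
#' metadata the inference machinery needs: state and parameter labels, the
#' per-parameter search upper bound `wmax` (the genetic algorithm samples
#' each parameter uniformly on \[0, wmax\]), an optional reference parameter
#' vector for benchmark problems, and optional conservation relations used
#' by tests.
#'
#' Third-party ("plugin") models register through this same contract and are
#' then usable everywhere a bundled model is: `simulate_model()`, the
#' criteria, the genetic algorithm and the robustness analysis.
#'
#' @param name model identifier (used on the command line).
#' @param state_names character vector of component labels.
#' @param param_names character vector of parameter labels.
#' @param rhs function `(state, params, t)` returning the derivative vector.
#' @param initial_state default initial concentrations.
#' @param wmax scalar or per-parameter upper search bound (> 0).
#' @param exact_params optional reference parameter vector (benchmarks).
#' @param conserved_sums optional list of index vectors whose component sums
#'   are constant along trajectories.
#' @param factor_map optional list of length-3 index vectors
#'   `(kon, koff, kcat)` describing enzymatic activation steps, consumed by
#'   [km_factor_errors()].
#'
#' @return An object of class `ode_model`.
#' @seealso [erk_model()], [g1s_model()], [simulate_model()]
#' @export
ode_model <- function(name, state_names, param_names, rhs, initial_state,
                      wmax, exact_params = NULL, conserved_sums = NULL,
                      factor_map = NULL) {
  if (!is.character(name) || length(name) != 1L)
    abort_validation("'name' must be a single string")
  if (!is.function(rhs))
    abort_validation("'rhs' must be a function(state, params, t)")
  n <- length(state_names)
  m <- length(param_names)
  if (length(initial_state) != n)
    abort_validation("length(initial_state) must equal length(state_names)")
  if (length(wmax) == 1L) wmax <- rep(as.numeric(wmax), m)
  if (length(wmax) != m)
    abort_validation("'wmax' must be a scalar or one bound per parameter")
  if (any(!is.finite(wmax)) || any(wmax <= 0))
    abort_validation("all 'wmax' must be positive")
  if (!is.null(exact_params)) {
    if (length(exact_params) != m)
      abort_validation("length(exact_params) must equal length(param_names)")
    exact_params <- setNames(as.numeric(exact_params), param_names)
  }
  if (!is.null(conserved_sums)) {
    for (idx in conserved_sums)
      if (any(idx < 1L | idx > n))
        abort_validation("conserved_sums indices out of range")
  }
  d0 <- rhs(as.numeric(initial_state),
            exact_params %||% rep(1, m), 0)
  if (length(d0) != n)
    abort_validation("rhs output length must equal the number of states")
  structure(list(name = name,
                 state_names = as.character(state_names),
                 param_names = as.character(param_names),
                 rhs = rhs,
                 initial_state = setNames(as.numeric(initial_state),
                                          state_names),
                 wmax = setNames(wmax, param_names),
                 exact_params = exact_params,
                 conserved_sums = conserved_sums,
                 factor_map = factor_map,
                 native_id = 0L),
            class = "ode_model")
}

#' @export
print.ode_model <- function(x, ...) {
  cat(sprintf("<ode_model> %s: %d states (%s), %d parameters\n", x$name,
              length(x$state_names), paste(x$state_names, collapse = ", "),
              length(x$param_names)))
  invisible(x)
}

#' Six-species ERK kinase activation module
#'
#' Mass-action model of the distributive dual phosphorylation of ERK by
#' activated MEK (MEKpp).  MEKpp binds ERK, releases mono-phosphorylated
#' ERKp, and a second independent collision produces dual-phosphorylated
#' ERKpp:
#' \deqn{M + E <-> M.E -> M + Ep,\quad M + Ep <-> M.Ep -> M + Epp}
#' States are `M` (MEKpp), `E` (ERK), the complexes `M.E`, `M.Ep`, and the
#' phosphoforms `Ep`, `Epp`; default initial state `[0.165, 5, 0, 0, 0, 0]`.
#' Parameters are the binding, unbinding and catalytic constants of the two
#' activation steps; every parameter has search bound `wmax = 300`.
#'
#' Total MEK (`M + M.E + M.Ep`) and total ERK (`E + M.E + Ep + M.Ep + Epp`)
#' are conserved.  The bundled reference rate constants are a synthetic
#' stand-in of literature magnitude for this module (the system is
#' moderately stiff at these rates); they define the benchmark's ground
#' truth for simulation studies, not measured biology.
#'
#' @return An [ode_model()].
#' @export
#' @examples
#' m <- erk_model()
#' m$initial_state
erk_model <- function() {
  rhs <- function(state, params, t) {
    M <- state[1]; E <- state[2]; ME <- state[3]
    Ep <- state[4]; MEp <- state[5]
    v_bind1 <- params[1] * M * E
    v_rel1 <- params[2] * ME
    v_cat1 <- params[3] * ME
    v_bind2 <- params[4] * M * Ep
    v_rel2 <- params[5] * MEp
    v_cat2 <- params[6] * MEp
    c(-v_bind1 + v_rel1 + v_cat1 - v_bind2 + v_rel2 + v_cat2,
      -v_bind1 + v_rel1,
      v_bind1 - v_rel1 - v_cat1,
      v_cat1 - v_bind2 + v_rel2,
      v_bind2 - v_rel2 - v_cat2,
      v_cat2)
  }
  m <- ode_model(
    name = "erk",
    state_names = c("M", "E", "M.E", "Ep", "M.Ep", "Epp"),
    param_names = c("kon1", "koff1", "kcat1", "kon2", "koff2", "kcat2"),
    rhs = rhs,
    initial_state = c(0.165, 5, 0, 0, 0, 0),
    wmax = 300,
    # synthetic stand-in reference rates (see package vignette)
    exact_params = c(16.7, 0.6, 0.35, 16.7, 0.6, 2.9),
    conserved_sums = list(MEK_total = c(1L, 3L, 5L),
                          ERK_total = c(2L, 3L, 4L, 5L, 6L)),
    factor_map = list(step1 = c(1L, 2L, 3L), step2 = c(4L, 5L, 6L)))
  m$native_id <- 1L
  m
}

#' Two-species G1/S transition module (pRB and E2F1)
#'
#' Bistable module of the mammalian G1/S transition: the transcription
#' factor E2F1 activates its own transcription and that of its inhibitor,
#' the tumour suppressor pRB, which in turn represses E2F1.
#' \deqn{dpRB/dt = k_1 \frac{E2F1}{K_{n1}+E2F1}\frac{J_{11}}{J_{11}+pRB}
#'   - \phi_{pRB}\, pRB}
#' \deqn{dE2F1/dt = k_p + k_2 \frac{a^2+E2F1^2}{K_{n2}^2+E2F1^2}
#'   \frac{J_{12}}{J_{12}+pRB} - \phi_{E2F1}\, E2F1}
#' Reference parameters `(k1 = 1, Kn1 = 0.5, J11 = 0.5, phi_pRB = 0.005,
#' kp = 0.05, k2 = 1.6, a = 0.04, Kn2 = 4, J12 = 5, phi_E2F1 = 0.1)`,
#' initial state `[pRB, E2F1] = [1, 5]`, and search bound `wmax = 5` for
#' all ten parameters.
#'
#' @return An [ode_model()].
#' @export
g1s_model <- function() {
  rhs <- function(state, params, t) {
    pRB <- state[1]; E2F1 <- state[2]
    c(params[1] * E2F1 / (params[2] + E2F1) *
        params[3] / (params[3] + pRB) - params[4] * pRB,
      params[5] + params[6] * (params[7]^2 + E2F1^2) /
        (params[8]^2 + E2F1^2) * params[9] / (params[9] + pRB) -
        params[10] * E2F1)
  }
  m <- ode_model(
    name = "g1s",
    state_names = c("pRB", "E2F1"),
    param_names = c("k1", "Kn1", "J11", "phi_pRB", "kp",
                    "k2", "a", "Kn2", "J12", "phi_E2F1"),
    rhs = rhs,
    initial_state = c(1, 5),
    wmax = 5,
    exact_params = c(1, 0.5, 0.5, 0.005, 0.05, 1.6, 0.04, 4, 5, 0.1))
  m$native_id <- 2L
  m
}

#' Look up a bundled model by name
#'
#' @param name `"erk"` or `"g1s"`.
#' @return An [ode_model()].
#' @export
get_model <- function(name) {
  switch(name,
         erk = erk_model(),
         g1s = g1s_model(),
         abort_validation(sprintf("unknown model '%s' (bundled: erk, g1s)",
                                  name)))
}
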