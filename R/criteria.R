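# The sixteen least-squares fitness criteria.
#
# Terms are identified by the numbers 2..17: discrete value error (2
# absolute / 3 relative), discrete slope error (4/5), discrete
# second-derivative error (6/7), discrete curvature-maximum ("roughness")
# error (8/9), and their continuous counterparts (10..17) in which sums
# over measurement points become composite-Simpson integrals over the
# whole observation window and the roughness maxima are taken over the
# sampling grid.  Each named criterion is an equal-weight sum of terms:
#
#   DAE1 (2)        DAE2 (2,4)      DAE3 (2,4,6)      DAE4 (2,4,8)
#   DRE1 (3)        DRE2 (3,5)      DRE3 (3,5,7)      DRE4 (3,5,9)
#   CAE1 (10)       CAE2 (10,12)    CAE3 (10,12,14)   CAE4 (10,12,16)
#   CRE1 (11)       CRE2 (11,13)    CRE3 (11,13,15)   CRE4 (11,13,17)

CRITERION_TABLE <- list(
  DAE1 = 2L,  DAE2 = c(2L, 4L),  DAE3 = c(2L, 4L, 6L),  DAE4 = c(2L, 4L, 8L),
  DRE1 = 3L,  DRE2 = c(3L, 5L),  DRE3 = c(3L, 5L, 7L),  DRE4 = c(3L, 5L, 9L),
  CAE1 = 10L, CAE2 = c(10L, 12L), CAE3 = c(10L, 12L, 14L),
  CAE4 = c(10L, 12L, 16L),
  CRE1 = 11L, CRE2 = c(11L, 13L), CRE3 = c(11L, 13L, 15L),
  CRE4 = c(11L, 13L, 17L))

#' The sixteen fitness criteria
#'
#' `criterion_ids()` lists the available criterion identifiers;
#' `criterion_spec()` resolves one identifier into its component error
#' terms.  Identifiers follow the pattern `[DC][AR]E[1-4]`: discrete or
#' continuous, absolute or relative error, using function values only (1),
#' adding first derivatives (2), adding second-derivative errors (3), or
#' adding a curvature-maximum roughness term (4).
#'
#' @param id criterion identifier, e.g. `"CAE4"`.
#' @param weights optional nonnegative per-term weights (default all 1).
#'
#' @return `criterion_spec()` returns a `criterion_spec` object with fields
#'   `id`, `mode` (`"discrete"`/`"continuous"`), `error_kind`
#'   (`"absolute"`/`"relative"`), `components` (term numbers) and `weights`.
#' @export
#' @examples
#' criterion_spec("CAE3")$components  # 10, 12, 14
criterion_spec <- function(id, weights = NULL) {
  if (!is.character(id) || length(id) != 1L || is.na(match(id, names(CRITERION_TABLE))))
    abort_validation(sprintf("unknown criterion id '%s'", paste(id, collapse = ",")))
  comp <- CRITERION_TABLE[[id]]
  weights <- weights %||% rep(1, length(comp))
  if (length(weights) != length(comp) || any(weights < 0) || anyNA(weights))
    abort_validation("'weights' must be nonnegative, one per component term")
  structure(list(id = id,
                 mode = if (startsWith(id, "D")) "discrete" else "continuous",
                 error_kind = if (substr(id, 2L, 2L) == "A") "absolute" else "relative",
                 components = comp,
                 weights = as.numeric(weights)),
            class = "criterion_spec")
}

#' @rdname criterion_spec
#' @export
criterion_ids <- function() names(CRITERION_TABLE)

default_criterion_settings <- function() {
  list(n_panels = 200L,        # Simpson panels over the observation window
       sim_grid_points = NULL, # continuous criteria: spline the solution on
                               # the measurement grid (NULL) or on a dense
                               # uniform grid with this many points
       guard = 1e-12,          # |denominator| threshold for relative terms
       zero_policy = "exclude",
       boundary = "natural",
       rtol = 1e-6, atol = 1e-9, max_steps = 100000L,
       quiet = FALSE)
}

check_same_grid <- function(sim, obs) {
  if (length(sim$times) != length(obs$times) ||
      max(abs(sim$times - obs$times)) > 1e-12 * max(1, max(abs(obs$times))))
    abort_validation("simulation and observation time grids differ")
  if (nrow(sim$values) != nrow(obs$values))
    abort_validation("simulation and observation component sets differ")
}

# shared kernel: sum of squared (optionally relative) differences with a
# division guard; sim/obs are (points x components) matrices
sq_error_sum <- function(sim, obs, kind, guard, zero_policy, w = NULL,
                         what = "observation value") {
  d <- sim - obs
  if (kind == "relative") {
    bad <- abs(obs) <= guard
    if (any(bad)) {
      if (zero_policy == "error") {
        ij <- which(bad, arr.ind = TRUE)[1L, ]
        abort_guard(sprintf(
          "%s is (near) zero for component %d at point %d; relative error undefined",
          what, ij[2L], ij[1L]))
      }
      d[bad] <- 0
      obs[bad] <- 1
    }
    d <- d / obs
  }
  if (is.null(w)) sum(d * d) else sum(w * rowSums(d * d))
}

#' Discrete value-error criterion terms
#'
#' Sum over components and measurement points of the squared difference
#' between simulated and observed concentrations; the relative kind divides
#' each difference by the observed value.
#'
#' @param sim,obs [timeseries()] objects on identical time grids.
#' @param kind `"absolute"` or `"relative"`.
#' @param guard magnitude below which a relative-error denominator counts
#'   as zero.
#' @param zero_policy `"error"` (default: raise a division-guard error
#'   naming the offending entry) or `"exclude"` (drop those entries).
#' @return nonnegative scalar.
#' @export
discrete_value_error <- function(sim, obs, kind = c("absolute", "relative"),
                                 guard = 1e-12,
                                 zero_policy = c("error", "exclude")) {
  kind <- match.arg(kind); zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(sim, "timeseries"), inherits(obs, "timeseries"))
  check_same_grid(sim, obs)
  sq_error_sum(t(sim$values), t(obs$values), kind, guard, zero_policy)
}

#' Discrete derivative-error criterion terms
#'
#' As [discrete_value_error()] but comparing first (`order = 1`) or second
#' (`order = 2`) derivatives.  Derivatives of both series are taken from
#' their natural cubic splines evaluated at the shared measurement knots;
#' no finite-difference rule is used.
#'
#' @inheritParams discrete_value_error
#' @param order 1 or 2.
#' @param boundary spline boundary condition.
#' @return nonnegative scalar.
#' @export
discrete_derivative_error <- function(sim, obs, order,
                                      kind = c("absolute", "relative"),
                                      boundary = "natural", guard = 1e-12,
                                      zero_policy = c("error", "exclude")) {
  kind <- match.arg(kind); zero_policy <- match.arg(zero_policy)
  if (!order %in% 1:2) abort_validation("'order' must be 1 or 2")
  check_same_grid(sim, obs)
  dsim <- spline_on_grid(sim, sim$times, orders = order, boundary = boundary)[[1L]]
  dobs <- spline_on_grid(obs, obs$times, orders = order, boundary = boundary)[[1L]]
  sq_error_sum(dsim, dobs, kind, guard, zero_policy,
               what = sprintf("observed derivative (order %d)", order))
}

# per-component maximal curvature magnitude, optionally scaled pointwise by
# the trajectory value (vals0); d2/vals0 are (points x components)
rough_measure <- function(d2, vals0, kind, guard) {
  v <- abs(d2)
  if (kind == "relative") {
    den <- abs(vals0)
    v[den <= guard] <- NA
    v <- v / den
  }
  mx <- suppressWarnings(apply(v, 2L, max, na.rm = TRUE))
  mx[!is.finite(mx)] <- 0
  mx
}

#' Roughness of a simulated trajectory
#'
#' Diagnostic measure of solution roughness: the per-component maximum of
#' the absolute second derivative (relative kind: second derivative scaled
#' pointwise by the trajectory value), summed over components.  The
#' discrete mode takes the maximum over the measurement knots, the
#' continuous mode over the Simpson sampling grid ("the maximal value of a
#' function over \[a, b\] is the maximum over the sampling points").  This
#' is a property of the simulation alone; the Table-style criterion terms
#' 8/9/16/17 compare this measure between simulation and observation so
#' that a perfect fit scores zero (see the package vignette).
#'
#' @param x a [timeseries()] or a `continuous_trajectory`.
#' @param kind `"absolute"` or `"relative"`.
#' @param mode `"discrete"` or `"continuous"`.
#' @param n_panels Simpson panels defining the continuous sampling grid.
#' @inheritParams discrete_value_error
#' @return nonnegative scalar.
#' @export
roughness_penalty <- function(x, kind = c("absolute", "relative"),
                              mode = c("discrete", "continuous"),
                              n_panels = 200L, guard = 1e-12,
                              zero_policy = c("error", "exclude")) {
  kind <- match.arg(kind); mode <- match.arg(mode)
  zero_policy <- match.arg(zero_policy)
  traj <- if (inherits(x, "continuous_trajectory")) x else fit_spline(x)
  grid <- if (mode == "discrete") traj$knots else
    seq(traj$span[1], traj$span[2], length.out = check_count(n_panels, "n_panels", 2L) + 1L)
  d2 <- eval_trajectory(traj, grid, order = 2L)
  v0 <- eval_trajectory(traj, grid, order = 0L)
  if (kind == "relative" && zero_policy == "error" && any(abs(v0) <= guard))
    abort_guard("trajectory value is (near) zero; relative roughness undefined")
  sum(rough_measure(d2, v0, kind, guard))
}

# criterion terms 8/9/16/17: squared difference of the per-component
# curvature maxima of simulation and observation
rough_error <- function(sim_d2, sim_v0, obs_d2, obs_v0, kind, guard,
                        zero_policy) {
  rs <- rough_measure(sim_d2, sim_v0, "absolute", guard)
  ro <- rough_measure(obs_d2, obs_v0, "absolute", guard)
  d <- rs - ro
  if (kind == "relative") {
    bad <- ro <= guard
    if (any(bad) && zero_policy == "error")
      abort_guard("observed curvature maximum is zero; relative roughness error undefined")
    d[bad] <- 0
    ro[bad] <- 1
    d <- d / ro
  }
  sum(d * d)
}

#' Composite Simpson's rule
#'
#' Integrates a function (or equally spaced samples) over `[a, b]` with an
#' even number of panels.  Exact for cubic polynomials.
#'
#' @param f function of one (vectorized) argument, or a numeric vector of
#'   `n_panels + 1` equally spaced samples.
#' @param a,b integration limits.
#' @param n_panels even panel count, >= 2.
#' @return the integral estimate.
#' @export
#' @examples
#' simpson_integral(function(t) t^3, 0, 1, 2)  # exactly 0.25
simpson_integral <- function(f, a, b, n_panels = 200L) {
  n_panels <- check_count(n_panels, "n_panels", 2L)
  if (n_panels %% 2L != 0L)
    abort_validation("'n_panels' must be even")
  grid <- seq(a, b, length.out = n_panels + 1L)
  vals <- if (is.function(f)) f(grid) else f
  if (length(vals) != n_panels + 1L)
    abort_validation("sample vector must have n_panels + 1 entries")
  sum(simpson_weights(a, b, n_panels) * vals)
}

simpson_weights <- function(a, b, n_panels) {
  h <- (b - a) / n_panels
  w <- rep(c(2, 4), length.out = n_panels + 1L)
  w[1L] <- 1; w[n_panels + 1L] <- 1
  w * h / 3
}

#' Continuous (integral) error between two spline trajectories
#'
#' Integrates over the shared observation window, by composite Simpson's
#' rule, the squared pointwise difference of the order-th derivatives of
#' two spline trajectories, summed over components.  The relative kind
#' divides the pointwise difference by the observed quantity of the same
#' order.
#'
#' @param sim_traj,obs_traj `continuous_trajectory` objects; the simulation
#'   span must cover the observation span, over which the integral is taken.
#' @param order 0, 1 or 2.
#' @inheritParams discrete_value_error
#' @param n_panels even number of Simpson panels (>= 2).
#' @return nonnegative scalar.
#' @export
continuous_error <- function(sim_traj, obs_traj, order = 0L,
                             kind = c("absolute", "relative"),
                             n_panels = 200L, guard = 1e-12,
                             zero_policy = c("error", "exclude")) {
  kind <- match.arg(kind); zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(sim_traj, "continuous_trajectory"),
            inherits(obs_traj, "continuous_trajectory"))
  if (!order %in% 0:2) abort_validation("'order' must be 0, 1 or 2")
  n_panels <- check_count(n_panels, "n_panels", 2L)
  if (n_panels %% 2L != 0L)
    abort_validation("'n_panels' must be even")
  a <- obs_traj$span[1]; b <- obs_traj$span[2]
  tol <- 1e-9 * max(1, b - a)
  if (sim_traj$span[1] > a + tol || sim_traj$span[2] < b - tol)
    abort_validation("simulation span does not cover the observation span")
  if (ncol(sim_traj$values) != ncol(obs_traj$values))
    abort_validation("component sets differ")
  grid <- seq(a, b, length.out = n_panels + 1L)
  ds <- eval_trajectory(sim_traj, grid, order = order)
  do <- eval_trajectory(obs_traj, grid, order = order)
  sq_error_sum(ds, do, kind, guard, zero_policy,
               w = simpson_weights(a, b, n_panels),
               what = sprintf("observed trajectory (order %d)", order))
}

fitness_value <- function(total, per_term, failed = FALSE) {
  structure(list(total = total, per_term = per_term, failed = failed),
            class = "fitness_value")
}

#' @export
print.fitness_value <- function(x, ...) {
  if (x$failed) cat("<fitness_value> FAILED simulation (total = Inf)\n")
  else cat(sprintf("<fitness_value> total = %g (%s)\n", x$total,
                   paste(sprintf("%s=%g", names(x$per_term), x$per_term),
                         collapse = ", ")))
  invisible(x)
}

#' Evaluate a fitness criterion on a simulation/observation pair
#'
#' Dispatches to the criterion's component terms and combines them into a
#' single fitness value (weighted sum; default weights 1).  For discrete
#' criteria `sim` must share the observation's time grid; for continuous
#' criteria `sim` is usually a denser simulation (default 101 points) and
#' both series are expanded into natural cubic splines before the Simpson
#' integrals are taken over the observation window.
#'
#' Relative criteria are undefined where the observed quantity is zero
#' (e.g. ERK complexes at t = 0).  The default policy excludes those
#' entries from the sums and reports once per call; set
#' `settings$zero_policy = "error"` to make them hard errors.
#'
#' A failed simulation (`sim_failure`) yields `failed = TRUE` and
#' `total = Inf`, which the genetic algorithm treats as worst fitness.
#'
#' @param spec a [criterion_spec()].
#' @param sim simulated [timeseries()] or a `sim_failure`.
#' @param obs observed [timeseries()].
#' @param settings optional list overriding `n_panels` (200), `guard`
#'   (1e-12), `zero_policy` (`"exclude"`), `boundary` (`"natural"`) and
#'   `quiet`.
#' @return A `fitness_value` with fields `total`, `per_term` and `failed`.
#' @export
evaluate_criterion <- function(spec, sim, obs, settings = list()) {
  stopifnot(inherits(spec, "criterion_spec"))
  s <- modifyList(default_criterion_settings(), settings)
  if (is_sim_failure(sim))
    return(fitness_value(Inf, setNames(rep(NA_real_, length(spec$components)),
                                       paste0("eq", spec$components)),
                         failed = TRUE))
  stopifnot(inherits(sim, "timeseries"), inherits(obs, "timeseries"))

  if (spec$error_kind == "relative" && s$zero_policy == "exclude" &&
      !isTRUE(s$quiet)) {
    nzero <- sum(abs(obs$values) <= s$guard)
    if (nzero > 0)
      message(sprintf(
        "evaluate_criterion(%s): %d zero observation value(s); relative terms skip the affected entries",
        spec$id, nzero))
  }

  per <- numeric(0)
  if (spec$mode == "discrete") {
    check_same_grid(sim, obs)
    need_d <- any(spec$components %in% c(4:9))
    if (need_d) {
      dsim <- spline_on_grid(sim, sim$times, orders = 0:2, boundary = s$boundary)
      dobs <- spline_on_grid(obs, obs$times, orders = 0:2, boundary = s$boundary)
    }
    for (e in spec$components) {
      v <- switch(as.character(e),
        "2" = discrete_value_error(sim, obs, "absolute", s$guard, s$zero_policy),
        "3" = discrete_value_error(sim, obs, "relative", s$guard, s$zero_policy),
        "4" = sq_error_sum(dsim$d1, dobs$d1, "absolute", s$guard, s$zero_policy),
        "5" = sq_error_sum(dsim$d1, dobs$d1, "relative", s$guard, s$zero_policy,
                           what = "observed slope"),
        "6" = sq_error_sum(dsim$d2, dobs$d2, "absolute", s$guard, s$zero_policy),
        "7" = sq_error_sum(dsim$d2, dobs$d2, "relative", s$guard, s$zero_policy,
                           what = "observed second derivative"),
        "8" = rough_error(dsim$d2, dsim$d0, dobs$d2, dobs$d0, "absolute",
                          s$guard, s$zero_policy),
        "9" = rough_error(dsim$d2, dsim$d0, dobs$d2, dobs$d0, "relative",
                          s$guard, s$zero_policy),
        abort_validation(sprintf("term %d is not a discrete term", e)))
      per <- c(per, v)
    }
  } else {
    sim_traj <- fit_spline(sim, boundary = s$boundary)
    obs_traj <- fit_spline(obs, boundary = s$boundary)
    a <- obs_traj$span[1]; b <- obs_traj$span[2]
    grid <- seq(a, b, length.out = s$n_panels + 1L)
    gs <- lapply(0:2, function(o) eval_trajectory(sim_traj, grid, o))
    go <- lapply(0:2, function(o) eval_trajectory(obs_traj, grid, o))
    w <- simpson_weights(a, b, s$n_panels)
    for (e in spec$components) {
      v <- switch(as.character(e),
        "10" = sq_error_sum(gs[[1]], go[[1]], "absolute", s$guard, s$zero_policy, w),
        "11" = sq_error_sum(gs[[1]], go[[1]], "relative", s$guard, s$zero_policy, w),
        "12" = sq_error_sum(gs[[2]], go[[2]], "absolute", s$guard, s$zero_policy, w),
        "13" = sq_error_sum(gs[[2]], go[[2]], "relative", s$guard, s$zero_policy, w,
                            what = "observed slope"),
        "14" = sq_error_sum(gs[[3]], go[[3]], "absolute", s$guard, s$zero_policy, w),
        "15" = sq_error_sum(gs[[3]], go[[3]], "relative", s$guard, s$zero_policy, w,
                            what = "observed second derivative"),
        "16" = rough_error(gs[[3]], gs[[1]], go[[3]], go[[1]], "absolute",
                           s$guard, s$zero_policy),
        "17" = rough_error(gs[[3]], gs[[1]], go[[3]], go[[1]], "relative",
                           s$guard, s$zero_policy),
        abort_validation(sprintf("term %d is not a continuous term", e)))
      per <- c(per, v)
    }
  }
  names(per) <- paste0("eq", spec$components)
  fitness_value(sum(spec$weights * per), per)
}
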