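#' Fit a piecewise-cubic spline to a discrete trajectory
#'
#' Builds, independently for every component on the shared knot grid, the
#' interpolating cubic spline in moment form: on each interval
#' `s_i(t) = a_i + b_i (t - t_i) + c_i (t - t_i)^2 + d_i (t - t_i)^3`, with
#' the second derivatives `M_i = S''(t_i)` obtained from the classical
#' tridiagonal moment system.  The spline is C2-continuous on the whole
#' span and is what the continuous fitness criteria (and the derivative
#' terms of the discrete criteria) evaluate.
#'
#' Three boundary conditions are supported:
#' * `"natural"` (default): `M_1 = M_m = 0`;
#' * `"parabolic"`: `M_1 = M_2` and `M_{m-1} = M_m`;
#' * `"cubic_runout"`: `M_1 = 2 M_2 - M_3` and `M_m = 2 M_{m-1} - M_{m-2}`.
#'
#' @param series a [timeseries()] with at least 3 knots (4 for
#'   `"cubic_runout"`).
#' @param boundary boundary condition.
#'
#' @return An object of class `continuous_trajectory` with fields `knots`,
#'   `values` (knots x components), `moments` (second derivatives at the
#'   knots), `coefficients` (interval x (a, b, c, d) x component array),
#'   `boundary`, `span` and `component_names`.
#' @export
#' @examples
#' sp <- fit_spline(timeseries(0:3, rbind(sin(0:3))))
#' eval_trajectory(sp, 1.5)
fit_spline <- function(series,
                       boundary = c("natural", "parabolic", "cubic_runout")) {
  stopifnot(inherits(series, "timeseries"))
  boundary <- match.arg(boundary)
  m <- length(series$times)
  min_knots <- if (boundary == "cubic_runout") 4L else 3L
  if (m < min_knots)
    abort_size(sprintf("'%s' boundary needs at least %d knots, got %d",
                       boundary, min_knots, m))
  if (any(diff(series$times) <= 0))
    abort_validation("knot times must be strictly increasing (no duplicates)")
  bcode <- match(boundary, c("natural", "parabolic", "cubic_runout")) - 1L
  y <- t(series$values)                      # knots x components
  M <- spline_moments_cpp(series$times, y, bcode)

  h <- diff(series$times)
  ncomp <- ncol(y)
  coef <- array(NA_real_, dim = c(m - 1L, 4L, ncomp),
                dimnames = list(NULL, c("a", "b", "c", "d"),
                                series$component_names))
  for (cc in seq_len(ncomp)) {
    i <- seq_len(m - 1L)
    coef[, "a", cc] <- y[i, cc]
    coef[, "b", cc] <- diff(y[, cc]) / h - h * (2 * M[i, cc] + M[i + 1L, cc]) / 6
    coef[, "c", cc] <- M[i, cc] / 2
    coef[, "d", cc] <- (M[i + 1L, cc] - M[i, cc]) / (6 * h)
  }
  structure(list(knots = series$times, values = y, moments = M,
                 coefficients = coef, boundary = boundary,
                 span = range(series$times),
                 component_names = series$component_names),
            class = "continuous_trajectory")
}

#' @export
print.continuous_trajectory <- function(x, ...) {
  cat(sprintf("<continuous_trajectory> %d component(s), %d knots on [%g, %g], %s boundary\n",
              ncol(x$values), length(x$knots), x$span[1], x$span[2],
              x$boundary))
  invisible(x)
}

#' Evaluate a spline trajectory (value or derivatives)
#'
#' @param traj a `continuous_trajectory` from [fit_spline()].
#' @param t evaluation time(s), inside the trajectory span; extrapolation
#'   is refused.
#' @param order 0 (value), 1 (first derivative) or 2 (second derivative).
#'
#' @return For scalar `t`, a named vector with one entry per component;
#'   for vector `t`, a `length(t)` x components matrix.
#' @export
eval_trajectory <- function(traj, t, order = 0L) {
  stopifnot(inherits(traj, "continuous_trajectory"))
  if (!order %in% 0:2)
    abort_validation("'order' must be 0, 1 or 2")
  if (!is.numeric(t) || length(t) < 1L || anyNA(t))
    abort_validation("'t' must be numeric without missing values")
  tol <- 1e-9 * max(1, diff(traj$span))
  if (any(t < traj$span[1] - tol) || any(t > traj$span[2] + tol))
    abort_extrapolation(sprintf(
      "evaluation time outside the fitted span [%g, %g]",
      traj$span[1], traj$span[2]))
  out <- spline_eval_cpp(traj$knots, traj$values, traj$moments,
                         as.numeric(t), as.integer(order))
  colnames(out) <- traj$component_names
  if (length(t) == 1L) out[1L, ] else out
}

# spline fit + evaluation on an arbitrary grid for internal use
spline_on_grid <- function(series, grid, orders = 0:2, boundary = "natural") {
  traj <- fit_spline(series, boundary = boundary)
  setNames(lapply(orders, function(o) {
    out <- spline_eval_cpp(traj$knots, traj$values, traj$moments,
                           as.numeric(grid), as.integer(o))
    colnames(out) <- traj$component_names
    out
  }), paste0("d", orders))
}
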