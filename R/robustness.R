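#' Perturbation configuration for robustness analysis
#'
#' @param mu perturbation strength: each parameter is multiplied by
#'   `1 + mu * N(0, 1)` independently (0.2 for the bundled benchmarks).
#' @param n_perturbations ensemble size (reference protocol: 5000).
#' @param seed random seed.
#' @param resample_on_invalid redraw a coordinate whose perturbed value is
#'   not positive (at most 100 attempts, then flagged).
#' @return A `perturbation_config` object.
#' @export
perturbation_config <- function(mu = 0.2, n_perturbations = 5000L, seed = 1L,
                                resample_on_invalid = TRUE) {
  check_number(mu, "mu", lower = 0)
  n_perturbations <- check_count(n_perturbations, "n_perturbations", 1L)
  seed <- check_count(seed, "seed", 0L)
  structure(list(mu = mu, n_perturbations = n_perturbations, seed = seed,
                 resample_on_invalid = isTRUE(resample_on_invalid)),
            class = "perturbation_config")
}

#' Multiplicative Gaussian parameter perturbation
#'
#' Draws `theta_i * (1 + mu * N(0, 1))` independently per coordinate,
#' using the current RNG state (seed management belongs to the caller;
#' [robustness_analysis()] seeds once from its config).
#'
#' @param theta strictly positive parameter vector.
#' @param config a [perturbation_config()].
#' @return Perturbed parameter vector; attribute `"invalid"` is `TRUE` if
#'   a coordinate stayed nonpositive after 100 redraws.
#' @export
perturb_parameters <- function(theta, config) {
  stopifnot(inherits(config, "perturbation_config"))
  if (any(theta <= 0))
    abort_validation("'theta' must be strictly positive")
  out <- theta * (1 + config$mu * rnorm(length(theta)))
  invalid <- FALSE
  if (config$resample_on_invalid && config$mu > 0) {
    for (attempt in seq_len(100L)) {
      bad <- out <= 0
      if (!any(bad)) break
      out[bad] <- theta[bad] * (1 + config$mu * rnorm(sum(bad)))
    }
    invalid <- any(out <= 0)
  }
  if (invalid) attr(out, "invalid") <- TRUE
  out
}

#' Monte-Carlo robustness analysis of a fitted model
#'
#' Simulates the model at `theta` (the unperturbed reference trajectory
#' `x_ij`), then repeatedly perturbs the parameters by [perturb_parameters()],
#' re-simulates, and scores each perturbation by the mean relative
#' deviation of the perturbed trajectory from the reference one over all
#' components and sampling times (entries with `|x_ij|` below the guard
#' are skipped).  Robustness is the ensemble mean of this simulation error
#' -- a Monte-Carlo estimate of the probability-weighted average over the
#' perturbation set -- with its standard deviation as a fluctuation
#' measure.  The parameter variation of each draw,
#' `eps_l = mean_i |theta_i^p - theta_i| / theta_i`, is summarized the
#' same way.  Perturbed simulations that blow up are counted in
#' `n_failed` and excluded from the summaries.
#'
#' @param model an [ode_model()].
#' @param theta parameter vector of the fitted model (strictly positive).
#' @param obs_times sampling times for the trajectory comparison.
#' @param config a [perturbation_config()].
#' @param guard relative-deviation denominator guard.
#' @param rtol,atol,max_steps solver options.
#' @return A `robustness_report`: `mean_sim_error`, `std_sim_error`,
#'   `mean_variation`, `std_variation`, `n_failed`, `n_perturbations`,
#'   `mu`, `seed`.
#' @export
robustness_analysis <- function(model, theta, obs_times,
                                config = perturbation_config(),
                                guard = 1e-12, rtol = 1e-6, atol = 1e-9,
                                max_steps = 100000L) {
  stopifnot(inherits(model, "ode_model"),
            inherits(config, "perturbation_config"))
  base <- simulate_model(model, theta, obs_times, rtol = rtol, atol = atol,
                         max_steps = max_steps)
  if (is_sim_failure(base))
    abort_odeinfer(paste("unperturbed simulation failed:", base$message),
                   "odeinfer_simulation_error")
  x <- base$values
  use <- abs(x) > guard

  set.seed(config$seed)
  sim_err <- rep(NA_real_, config$n_perturbations)
  variation <- rep(NA_real_, config$n_perturbations)
  n_failed <- 0L
  for (l in seq_len(config$n_perturbations)) {
    thp <- perturb_parameters(theta, config)
    pert <- simulate_model(model, thp, obs_times, rtol = rtol, atol = atol,
                           max_steps = max_steps)
    if (is_sim_failure(pert) || isTRUE(attr(thp, "invalid"))) {
      n_failed <- n_failed + 1L
      next
    }
    sim_err[l] <- mean(abs(pert$values[use] - x[use]) / abs(x[use]))
    variation[l] <- mean(abs(thp - theta) / theta)
  }
  ok <- !is.na(sim_err)
  structure(list(mean_sim_error = mean(sim_err[ok]),
                 std_sim_error = if (sum(ok) > 1L) sd(sim_err[ok]) else 0,
                 mean_variation = mean(variation[ok]),
                 std_variation = if (sum(ok) > 1L) sd(variation[ok]) else 0,
                 n_failed = n_failed,
                 n_perturbations = config$n_perturbations,
                 mu = config$mu, seed = config$seed),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf(
    "<robustness_report> mu = %g, n = %d (%d failed): sim error %.4g (STD %.4g), variation %.4g (STD %.4g)\n",
    x$mu, x$n_perturbations, x$n_failed, x$mean_sim_error, x$std_sim_error,
    x$mean_variation, x$std_variation))
  invisible(x)
}

#' Rank criteria by the robustness of their fitted models
#'
#' Takes, per criterion, the robustness reports of its top-k estimate sets,
#' averages the summaries across the k sets, and ranks criteria by
#' ascending mean simulation error (a model is more stable when both the
#' mean and the STD of its simulation errors are smaller).
#'
#' @param reports_by_criterion named list: criterion id -> list of
#'   `robustness_report` objects (one per estimate set).
#' @return A data frame sorted by `mean_sim_error` with one row per
#'   criterion and a `rank` column.
#' @export
robustness_compare <- function(reports_by_criterion) {
  if (!is.list(reports_by_criterion) || length(reports_by_criterion) == 0L ||
      is.null(names(reports_by_criterion)) ||
      any(names(reports_by_criterion) == ""))
    abort_validation("'reports_by_criterion' must be a non-empty named list")
  rows <- lapply(names(reports_by_criterion), function(id) {
    reps <- reports_by_criterion[[id]]
    if (inherits(reps, "robustness_report")) reps <- list(reps)
    if (length(reps) == 0L ||
        !all(vapply(reps, inherits, logical(1L), "robustness_report")))
      abort_validation(sprintf("entry '%s' must contain robustness reports", id))
    avg <- function(field) mean(vapply(reps, `[[`, numeric(1L), field))
    data.frame(criterion = id,
               mean_sim_error = avg("mean_sim_error"),
               std_sim_error = avg("std_sim_error"),
               mean_variation = avg("mean_variation"),
               std_variation = avg("std_variation"),
               n_sets = length(reps))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_sim_error), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
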