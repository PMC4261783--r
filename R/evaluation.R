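#' Select the k best estimates
#'
#' @param estimates an `estimate_set` (already sorted by ascending fitness).
#' @param k number of records to keep, `k <= length(estimates)`.
#' @return An `estimate_set` with the `k` lowest-fitness records.
#' @export
select_top_k <- function(estimates, k) {
  stopifnot(inherits(estimates, "estimate_set"))
  k <- check_count(k, "k", 1L)
  if (k > length(estimates))
    abort_validation(sprintf("k = %d exceeds the %d available estimates",
                             k, length(estimates)))
  idx <- seq_len(k)
  estimate_set(estimates$params[idx, , drop = FALSE],
               estimates$fitness[idx], estimates$criterion,
               seeds = estimates$seeds[idx],
               traces = estimates$traces[idx])
}

#' Accuracy of estimated parameters against a reference
#'
#' For each estimate set `theta^(j)` the estimation error is the mean over
#' parameters of the relative deviation from the reference `theta*`:
#' \deqn{E_j = \frac{1}{m}\sum_{i=1}^{m}
#'   \frac{|\theta_i^{(j)} - \theta_i^*|}{\theta_i^*}.}
#' The criterion's accuracy is the mean of `E_j` over the (typically
#' top-10) estimate sets, with their standard deviation as a stability
#' measure, and the per-parameter mean estimate scaled by the reference
#' value (unit one = perfect).
#'
#' @param estimates an `estimate_set` (usually from [select_top_k()]).
#' @param exact strictly positive reference parameter vector.
#' @return An `accuracy_report`: `criterion`, `mean_error`, `std_error`,
#'   `per_set_error`, `per_param_scaled_mean`.
#' @export
#' @examples
#' es <- estimate_set(rbind(c(1.1, 1.8)), fitness = 0)
#' accuracy(es, exact = c(1, 2))$mean_error  # 0.1
accuracy <- function(estimates, exact) {
  stopifnot(inherits(estimates, "estimate_set"))
  m <- ncol(estimates$params)
  if (length(exact) != m)
    abort_validation("'exact' length must match the number of parameters")
  if (any(!is.finite(exact)) || any(exact <= 0))
    abort_validation("'exact' must be strictly positive (relative error undefined at 0)")
  exact <- as.numeric(exact)
  rel <- abs(sweep(estimates$params, 2L, exact) ) / rep(exact, each = length(estimates))
  per_set <- rowMeans(rel)
  structure(list(criterion = estimates$criterion,
                 mean_error = mean(per_set),
                 std_error = if (length(per_set) > 1L) sd(per_set) else 0,
                 per_set_error = per_set,
                 per_param_scaled_mean =
                   colMeans(estimates$params) / exact),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %s: mean error %.4g (STD %.4g) over %d set(s)\n",
              x$criterion, x$mean_error, x$std_error, length(x$per_set_error)))
  invisible(x)
}

#' Steady-state factor errors for enzymatic activation steps
#'
#' For an activation step with binding, unbinding and catalytic constants
#' `(kon, koff, kcat)` the steady-state kinase level is governed by the
#' Michaelis factor `K_m = (koff + kcat) / kon` rather than by the
#' individual constants.  This scores estimates by the relative error of
#' `K_m` per step, averaged as in [accuracy()]: compensating changes
#' within a step's triple leave the factor error at zero even when the
#' per-parameter accuracy error is large.
#'
#' @param estimates an `estimate_set`.
#' @param exact reference parameter vector.
#' @param factor_map list of length-3 index vectors `(kon, koff, kcat)`;
#'   defaults to the model's `factor_map` when called with one.
#' @return A data frame with one row per factor: `factor`, `mean_error`,
#'   `std_error`.
#' @export
km_factor_errors <- function(estimates, exact, factor_map) {
  stopifnot(inherits(estimates, "estimate_set"))
  if (!is.list(factor_map) || length(factor_map) == 0L)
    abort_validation("'factor_map' must be a non-empty list of index triples")
  m <- ncol(estimates$params)
  for (tr in factor_map) {
    if (length(tr) != 3L || any(tr < 1L | tr > m))
      abort_validation("each factor_map entry must be 3 valid parameter indices (kon, koff, kcat)")
  }
  km <- function(theta, tr) (theta[tr[2L]] + theta[tr[3L]]) / theta[tr[1L]]
  out <- lapply(seq_along(factor_map), function(f) {
    tr <- factor_map[[f]]
    k_exact <- km(as.numeric(exact), tr)
    errs <- apply(estimates$params, 1L,
                  function(th) abs(km(th, tr) - k_exact) / k_exact)
    data.frame(factor = names(factor_map)[f] %||% paste0("factor", f),
               mean_error = mean(errs),
               std_error = if (length(errs) > 1L) sd(errs) else 0)
  })
  do.call(rbind, out)
}
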