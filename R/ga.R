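#' Genetic-algorithm configuration
#'
#' Defaults follow the classical binary-GA toolbox family: 100 individuals,
#' 300 generations, 20 Gray-coded bits per parameter on \[0, wmax\] (about
#' 1e-6 relative resolution), linear ranking with selective pressure 2,
#' stochastic universal sampling, single-point crossover at rate 0.7,
#' per-bit mutation at rate `0.7 / chromosome_length` (the toolbox-family
#' default; it plateaus by generation ~200 like the reference protocol --
#' raising it to ~`5 / L` searches the multimodal G1/S landscape much more
#' effectively at the cost of that plateau, see the vignette), and a
#' generation gap of 0.9 with fitness-based reinsertion (offspring replace
#' the worst parents, so the best parents always survive).
#'
#' @param population_size number of individuals (>= 2).
#' @param generations number of generations (>= 1).
#' @param bits_per_param bits per parameter in the chromosome.
#' @param crossover_rate probability of single-point crossover per pair.
#' @param mutation_rate per-bit flip probability; `NULL` means
#'   `0.7 / chromosome_length`, resolved once the model is known.
#' @param generation_gap fraction of the population reproduced each
#'   generation.
#' @param selective_pressure linear-ranking selective pressure in (1, 2\].
#' @param seed random seed; identical seeds give bit-identical runs.
#' @return A `ga_config` object.
#' @export
ga_config <- function(population_size = 100L, generations = 300L,
                      bits_per_param = 20L, crossover_rate = 0.7,
                      mutation_rate = NULL, generation_gap = 0.9,
                      selective_pressure = 2, seed = 1L) {
  population_size <- check_count(population_size, "population_size", 2L)
  generations <- check_count(generations, "generations", 1L)
  bits_per_param <- check_count(bits_per_param, "bits_per_param", 1L)
  check_number(crossover_rate, "crossover_rate", 0, 1)
  if (!is.null(mutation_rate)) check_number(mutation_rate, "mutation_rate", 0, 1)
  check_number(generation_gap, "generation_gap", 0, 1)
  check_number(selective_pressure, "selective_pressure", 1, 2)
  seed <- check_count(seed, "seed", 0L)
  structure(list(population_size = population_size, generations = generations,
                 bits_per_param = bits_per_param,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 generation_gap = generation_gap,
                 selective_pressure = selective_pressure, seed = seed),
            class = "ga_config")
}

#' Gray-coded binary encoding of parameter vectors
#'
#' `decode_params()` maps a 0/1 chromosome matrix (one row per individual)
#' to parameter vectors on \[0, wmax\]; `encode_params()` is its inverse up
#' to the encoding resolution `wmax / (2^bits - 1)`.  Uniform random bits
#' decode to a uniform distribution on the bound interval.
#'
#' @param bits integer 0/1 matrix, `bits_per_param * length(wmax)` columns.
#' @param wmax per-parameter upper bounds (lower bounds are 0).
#' @param bits_per_param bits per parameter.
#' @return `decode_params()`: numeric matrix of parameters (rows =
#'   individuals); `encode_params()`: 0/1 matrix of chromosomes.
#' @export
decode_params <- function(bits, wmax, bits_per_param) {
  m <- length(wmax)
  stopifnot(ncol(bits) == m * bits_per_param)
  out <- matrix(0, nrow(bits), m)
  pow <- 2^((bits_per_param - 1L):0L)
  denom <- 2^bits_per_param - 1
  for (j in seq_len(m)) {
    g <- bits[, (j - 1L) * bits_per_param + seq_len(bits_per_param), drop = FALSE]
    b <- g
    for (k in seq_len(bits_per_param)[-1L])
      b[, k] <- xor(b[, k - 1L] == 1L, g[, k] == 1L) * 1L
    out[, j] <- (b %*% pow) / denom * wmax[j]
  }
  colnames(out) <- names(wmax)
  out
}

#' @param params numeric matrix of parameter vectors (rows = individuals).
#' @rdname decode_params
#' @export
encode_params <- function(params, wmax, bits_per_param) {
  if (is.vector(params)) params <- matrix(params, nrow = 1L)
  m <- length(wmax)
  stopifnot(ncol(params) == m)
  denom <- 2^bits_per_param - 1
  bits <- matrix(0L, nrow(params), m * bits_per_param)
  for (j in seq_len(m)) {
    val <- round(params[, j] / wmax[j] * denom)
    val <- pmin(pmax(val, 0), denom)
    b <- matrix(0L, nrow(params), bits_per_param)
    for (k in bits_per_param:1L) {
      b[, k] <- val %% 2
      val <- val %/% 2
    }
    g <- b
    for (k in seq_len(bits_per_param)[-1L])
      g[, k] <- xor(b[, k - 1L] == 1L, b[, k] == 1L) * 1L
    bits[, (j - 1L) * bits_per_param + seq_len(bits_per_param)] <- g
  }
  bits
}

# Build the objective: parameter matrix (rows = candidates) -> fitness
# totals.  Native models take the compiled path (simulate + spline +
# criterion in C++); plugin models use the reference R implementation.
make_objective <- function(model, obs, spec, settings, fast = TRUE) {
  s <- modifyList(default_criterion_settings(), settings)
  s$quiet <- TRUE
  a <- min(obs$times); b <- max(obs$times)
  sim_times <- if (spec$mode == "discrete" || is.null(s$sim_grid_points))
    obs$times else seq(a, b, length.out = s$sim_grid_points)
  use_cpp <- fast && model$native_id > 0L

  if (use_cpp) {
    grid <- seq(a, b, length.out = s$n_panels + 1L)
    ob <- spline_on_grid(obs, obs$times, orders = 0:2, boundary = s$boundary)
    og <- spline_on_grid(obs, grid, orders = 0:2, boundary = s$boundary)
    function(theta) {
      if (is.vector(theta)) theta <- matrix(theta, nrow = 1L)
      vapply(seq_len(nrow(theta)), function(i) {
        fitness_native_cpp(model$native_id, theta[i, ], model$initial_state,
                           obs$times, ob$d0, ob$d1, ob$d2,
                           grid, og$d0, og$d1, og$d2,
                           as.integer(spec$components), spec$weights,
                           sim_times, s$rtol, s$atol,
                           as.integer(s$max_steps), s$guard)$total
      }, numeric(1L))
    }
  } else {
    function(theta) {
      if (is.vector(theta)) theta <- matrix(theta, nrow = 1L)
      vapply(seq_len(nrow(theta)), function(i) {
        sim <- simulate_model(model, theta[i, ], sim_times,
                              rtol = s$rtol, atol = s$atol,
                              max_steps = s$max_steps)
        evaluate_criterion(spec, sim, obs, settings = s)$total
      }, numeric(1L))
    }
  }
}

# linear-ranking fitness-assignment + stochastic universal sampling;
# objective values are minimized (Inf = failed simulation loses always)
sus_select <- function(objective_values, n_select, pressure) {
  n <- length(objective_values)
  ord <- order(objective_values, decreasing = TRUE)  # worst first
  rankfit <- numeric(n)
  rankfit[ord] <- 2 - pressure + 2 * (pressure - 1) * (seq_len(n) - 1) / (n - 1)
  p <- rankfit / sum(rankfit)
  cum <- cumsum(p)
  start <- runif(1) / n_select
  pointers <- start + (seq_len(n_select) - 1L) / n_select
  findInterval(pointers, cum, left.open = TRUE) + 1L
}

#' Run the genetic algorithm on one criterion
#'
#' Searches \[0, wmax\] per parameter for the vector minimizing the chosen
#' fitness criterion against the observations.  The initial population is
#' uniform on the bounds; each generation applies linear-ranking fitness
#' assignment, stochastic universal sampling, single-point crossover, bit
#' mutation and fitness-based reinsertion.  Failed simulations score
#' `Inf` and therefore lose every selection.  The best individual ever
#' seen is returned together with the per-generation best-so-far trace
#' (non-increasing by construction).
#'
#' @param model an [ode_model()].
#' @param obs observed [timeseries()].
#' @param spec a [criterion_spec()].
#' @param config a [ga_config()].
#' @param settings criterion/solver settings, see [evaluate_criterion()].
#' @param fast use the compiled fitness path for bundled models.
#' @return A `ga_result`: list with `par` (best parameters), `fitness`,
#'   `trace`, `criterion`, `seed`, `n_eval`.
#' @export
run_ga <- function(model, obs, spec, config = ga_config(), settings = list(),
                   fast = TRUE) {
  stopifnot(inherits(model, "ode_model"), inherits(obs, "timeseries"),
            inherits(spec, "criterion_spec"), inherits(config, "ga_config"))
  m <- length(model$param_names)
  nb <- config$bits_per_param
  L <- m * nb
  pm <- config$mutation_rate %||% (0.7 / L)
  np <- config$population_size
  objective <- make_objective(model, obs, spec, settings, fast = fast)

  set.seed(config$seed)
  pop <- matrix(sample(0:1, np * L, replace = TRUE), np, L)
  fit <- objective(decode_params(pop, model$wmax, nb))
  fit[is.na(fit)] <- Inf
  if (all(!is.finite(fit)))
    abort_odeinfer(
      "all individuals failed simulation in generation 0; check bounds/tolerances",
      "odeinfer_ga_error")

  best_i <- which.min(fit)
  best_fit <- fit[best_i]
  best_par <- decode_params(pop[best_i, , drop = FALSE], model$wmax, nb)[1L, ]
  trace <- numeric(config$generations)
  n_eval <- np

  n_off <- max(2L, round(config$generation_gap * np))
  if (n_off %% 2L == 1L) n_off <- n_off - 1L

  for (g in seq_len(config$generations)) {
    sel <- sus_select(fit, n_off, config$selective_pressure)
    sel <- sel[sample.int(n_off)]          # shuffle before pairing
    off <- pop[sel, , drop = FALSE]
    for (p in seq_len(n_off %/% 2L)) {
      if (L >= 2L && runif(1) < config$crossover_rate) {
        cp <- sample.int(L - 1L, 1L)
        i1 <- 2L * p - 1L; i2 <- 2L * p
        tmp <- off[i1, (cp + 1L):L]
        off[i1, (cp + 1L):L] <- off[i2, (cp + 1L):L]
        off[i2, (cp + 1L):L] <- tmp
      }
    }
    flip <- matrix(runif(n_off * L) < pm, n_off, L)
    off[flip] <- 1L - off[flip]

    off_fit <- objective(decode_params(off, model$wmax, nb))
    off_fit[is.na(off_fit)] <- Inf
    n_eval <- n_eval + n_off

    keep <- order(fit)[seq_len(np - n_off)]   # best parents survive
    pop <- rbind(pop[keep, , drop = FALSE], off)
    fit <- c(fit[keep], off_fit)

    gi <- which.min(fit)
    if (fit[gi] < best_fit) {
      best_fit <- fit[gi]
      best_par <- decode_params(pop[gi, , drop = FALSE], model$wmax, nb)[1L, ]
    }
    trace[g] <- best_fit
  }
  structure(list(par = best_par, fitness = best_fit, trace = trace,
                 criterion = spec$id, seed = config$seed, n_eval = n_eval,
                 config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %s: best fitness %g after %d evaluations (seed %d)\n",
              x$criterion, x$fitness, x$n_eval, x$seed))
  print(signif(x$par, 4))
  invisible(x)
}

#' Multi-start estimation and estimate sets
#'
#' Runs [run_ga()] from `n_starts` seeds (`config$seed`, `config$seed + 1`,
#' ...) and collects the final estimates into an `estimate_set` sorted by
#' ascending fitness.  A start whose run fails is recorded and skipped, not
#' fatal.
#'
#' @inheritParams run_ga
#' @param n_starts number of independent GA runs.
#' @return An `estimate_set`: `params` (one row per record, best first),
#'   `fitness`, `seeds`, `criterion`, plus the traces of every start.
#' @export
multi_start <- function(model, obs, spec, config = ga_config(),
                        n_starts = 100L, settings = list(), fast = TRUE) {
  n_starts <- check_count(n_starts, "n_starts", 1L)
  runs <- vector("list", n_starts)
  failed <- character(0)
  for (i in seq_len(n_starts)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    runs[[i]] <- tryCatch(
      run_ga(model, obs, spec, cfg, settings = settings, fast = fast),
      error = function(e) {
        failed <<- c(failed, sprintf("seed %d: %s", cfg$seed,
                                     conditionMessage(e)))
        NULL
      })
  }
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0L)
    abort_odeinfer(paste(c("every start failed:", failed), collapse = "\n"),
                   "odeinfer_ga_error")
  estimate_set(params = do.call(rbind, lapply(runs, `[[`, "par")),
               fitness = vapply(runs, `[[`, numeric(1L), "fitness"),
               criterion = spec$id,
               seeds = vapply(runs, `[[`, integer(1L), "seed"),
               traces = lapply(runs, `[[`, "trace"),
               failed_starts = failed)
}

#' @param params matrix of parameter vectors, one row per estimate.
#' @param fitness fitness totals, one per row.
#' @param criterion criterion id the fitness refers to.
#' @param seeds seed per record.
#' @param traces,failed_starts optional bookkeeping from [multi_start()].
#' @rdname multi_start
#' @export
estimate_set <- function(params, fitness, criterion = NA_character_,
                         seeds = NULL, traces = NULL,
                         failed_starts = character(0)) {
  if (is.vector(params)) params <- matrix(params, nrow = 1L)
  if (nrow(params) != length(fitness))
    abort_validation("one fitness value per parameter row required")
  ord <- order(fitness)
  structure(list(params = params[ord, , drop = FALSE],
                 fitness = fitness[ord],
                 criterion = criterion,
                 seeds = if (!is.null(seeds)) seeds[ord],
                 traces = if (!is.null(traces)) traces[ord],
                 failed_starts = failed_starts),
            class = "estimate_set")
}

#' @export
length.estimate_set <- function(x) nrow(x$params)

#' @export
print.estimate_set <- function(x, ...) {
  cat(sprintf("<estimate_set> %d record(s) for criterion %s; best fitness %g\n",
              length(x), x$criterion, x$fitness[1L]))
  invisible(x)
}
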