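# odeinfer

Parameter inference for ODE models of regulatory networks from sparse
time-course data, using **continuous** least-squares fitness criteria:
the discrete observations are expanded into a continuous representation of
the system dynamics by cubic-spline interpolation, and the objective may
match function values, first derivatives and second derivatives either at
the measurement points only or integrated over the whole observation
window.

It is aimed at systems biologists benchmarking inference criteria and
optimizers on kinetic models — the typical setting where a model
`dX/dt = f(X, θ)` has more unknown rate constants than there are measured
time points.

## What it implements

* **Models** (`ode_model()`): a plugin contract for dynamical systems with
  parameter bounds, plus two bundled benchmarks —
  `erk_model()`, six-species mass-action distributive dual phosphorylation
  of ERK by MEKpp (stiff; total MEK and ERK conserved), and
  `g1s_model()`, the two-species bistable pRB/E2F1 G1/S transition module.
* **Simulation** (`simulate_model()`): built-in stiff Rosenbrock 2(3)
  integrator plus an independent Dormand–Prince 5(4) pair; numerical
  blow-ups return a flagged `sim_failure`, never an error.
* **Splines** (`fit_spline()`, `eval_trajectory()`): moment-form cubic
  splines with natural, parabolic and cubic-runout boundaries, evaluable
  for value, slope and curvature.
* **Criteria** (`criterion_spec()`, `evaluate_criterion()`): the 16
  fitness functions `DAE1–4, DRE1–4, CAE1–4, CRE1–4` — discrete/continuous
  × absolute/relative, built from value, derivative, second-derivative and
  curvature-maximum (roughness) error terms; continuous integrals use
  composite Simpson's rule.
* **Inference** (`run_ga()`, `multi_start()`): binary Gray-coded genetic
  algorithm with linear ranking, stochastic universal sampling,
  single-point crossover, bit mutation and fitness-based reinsertion;
  uniform initialization on `[0, Wmax]`; fully seed-reproducible.
* **Evaluation** (`accuracy()`, `select_top_k()`, `km_factor_errors()`):
  mean relative estimation error of the top-k estimate sets against the
  reference parameters, and Michaelis-factor errors
  `K_m = (koff + kcat)/kon` for activation steps.
* **Robustness** (`robustness_analysis()`, `robustness_compare()`):
  Monte-Carlo perturbation `θ_i (1 + μ N(0,1))`, re-simulation, and
  mean/SD of the relative trajectory deviation over the ensemble.
* **CLI** (`odeinfer_cli()`, `inst/cli/odeinfer`): `generate`, `fit`,
  `evaluate`, `robustness` subcommands reading/writing CSV and JSON.

The methods vignette (`vignettes/continuous-criteria.Rmd`) documents the
formulas, the numerical choices, the synthetic-data conventions (the ERK
reference rates are a labelled synthetic stand-in) and the known
limitations.

## Worked example

```r
library(odeinfer)

# 1. synthetic "experimental" data: the G1/S standard simulation
ds <- make_standard_dataset(g1s_model())
print(ds$observations)
#> <timeseries> 2 component(s) x 7 time point(s), t in [0, 300]
#>   time      pRB      E2F1
#> 1    0 1.000000 5.0000000
#> 2   50 5.745708 6.3335105
#> 3  100 7.304590 4.3196647
#> 4  150 8.042001 2.8625732
#> 5  200 8.303260 1.4388593
#> 6  250 8.134494 0.7540761
#> 7  300 7.853339 0.6756866

# 2. fit the ten rate constants with the continuous absolute criterion
est <- multi_start(g1s_model(), ds$observations, criterion_spec("CAE1"),
                   ga_config(population_size = 50, generations = 100,
                             seed = 1),
                   n_starts = 5)
print(est)
#> <estimate_set> 5 record(s) for criterion CAE1; best fitness 1278.25

# 3. score the best estimates against the known reference parameters
acc <- accuracy(select_top_k(est, 3), g1s_model()$exact_params)
print(acc)
#> <accuracy_report> CAE1: mean error 17.42 (STD 4.702) over 3 set(s)
print(round(acc$per_param_scaled_mean, 2))
#>       k1      Kn1      J11  phi_pRB       kp       k2        a      Kn2
#>     3.08     3.93     7.63    20.78    33.56     2.44    94.51     0.45
#>      J12 phi_E2F1
#>     0.66    15.29

# 4. robustness of the fitted model under 20% parameter noise
rob <- robustness_analysis(g1s_model(), est$params[1, ], ds$measurement_times,
                           perturbation_config(mu = 0.2,
                                               n_perturbations = 500,
                                               seed = 1))
print(rob)
#> <robustness_report> mu = 0.2, n = 500 (0 failed): sim error 0.1662
#> (STD 0.1102), variation 0.1636 (STD 0.03752)
```

Reading the numbers: the best of five small GA runs still has CAE1 fitness
1278 (the reference parameters score ~1e-6), and the mean relative
parameter error 17.4 is dominated by the three reference parameters that
are tiny compared with the search bound (`phi_pRB = 0.005`, `a = 0.04`,
`kp = 0.05`; their scaled means 20.8, 94.5, 33.6 show exactly that).  The
robustness run says that 20% multiplicative parameter noise (mean drawn
variation 0.164 ≈ 0.2·√(2/π)) moves the fitted trajectory by 16.6% on
average at the measurement points, with no solver blow-ups in 500
perturbed simulations.  Deeper searches (`mutation_rate = 5/L`, more
generations, more starts) lower the fitness by orders of magnitude — see
the vignette.

The same pipeline from the shell:

```sh
Rscript inst/cli/odeinfer generate --model g1s --out g1s_obs.csv
Rscript inst/cli/odeinfer fit --model g1s --criterion CAE1 \
    --obs g1s_obs.csv --out run.json --starts 5 --pop 50 --gens 100 --seed 1
Rscript inst/cli/odeinfer evaluate --run run.json --top 3
Rscript inst/cli/odeinfer robustness --run run.json --mu 0.2 --n 500 --seed 1
```

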