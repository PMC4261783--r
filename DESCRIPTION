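Package: odeinfer
Title: Continuous-Criterion Parameter Inference for ODE Models of
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Daniel", "Keel", email = "dkeel@example.org",
           role = c("aut", "cre"))
Description: Infers kinetic parameters of ordinary-differential-equation
    models of biochemical regulatory networks from sparse time-course
    data.  Discrete observations are expanded into continuous system
    dynamics by cubic-spline interpolation (natural, parabolic or
    cubic-runout boundaries), and sixteen least-squares fitness
    criteria -- discrete and continuous, absolute and relative, using
    function values, first and second derivatives and a curvature
    (roughness) term -- drive a binary-encoded genetic algorithm.
    Bundles a six-species ERK kinase activation module and the
    two-species pRB/E2F1 G1/S transition module as benchmarks, a stiff
    Rosenbrock integrator, accuracy scoring of estimates against
    reference parameters, and Monte-Carlo robustness analysis under
    multiplicative Gaussian parameter perturbation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
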