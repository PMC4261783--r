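# Monte-Carlo robustness analysis under multiplicative Gaussian perturbation

test_that("perturbation config validates and mu = 0 is the identity", {
  expect_error(perturbation_config(mu = -0.1),
               class = "odeinfer_validation_error")
  expect_error(perturbation_config(n_perturbations = 0),
               class = "odeinfer_validation_error")
  theta <- c(1, 2, 3)
  set.seed(1)
  expect_identical(perturb_parameters(theta, perturbation_config(mu = 0)),
                   theta)
  expect_error(perturb_parameters(c(1, -1), perturbation_config()),
               class = "odeinfer_validation_error")
})

test_that("perturbations are unbiased and reproducible under a fixed seed", {
  cfg <- perturbation_config(mu = 0.2, resample_on_invalid = FALSE)
  theta <- rep(1, 4)
  set.seed(10)
  draws <- t(replicate(5000, perturb_parameters(theta, cfg)))
  se <- 0.2 / sqrt(5000)
  expect_true(all(abs(colMeans(draws) - 1) < 3 * se))
  set.seed(77); a <- replicate(10, perturb_parameters(theta, cfg))
  set.seed(77); b <- replicate(10, perturb_parameters(theta, cfg))
  expect_identical(a, b)
})

test_that("resampling keeps perturbed parameters positive", {
  cfg <- perturbation_config(mu = 1.5)   # huge strength: many invalid draws
  set.seed(3)
  for (i in 1:50) expect_true(all(perturb_parameters(c(0.1, 1), cfg) > 0))
})

test_that("zero-strength and zero-dynamics robustness errors vanish", {
  g1s <- g1s_model()
  tt <- seq(0, 300, by = 50)
  r0 <- robustness_analysis(g1s, g1s$exact_params, tt,
                            perturbation_config(mu = 0, n_perturbations = 5))
  expect_identical(r0$mean_sim_error, 0)
  expect_identical(r0$std_sim_error, 0)
  zm <- zero_model(2)
  rz <- robustness_analysis(zm, 1, 0:5,
                            perturbation_config(mu = 0.3,
                                                n_perturbations = 20))
  expect_identical(rz$mean_sim_error, 0)
  expect_gt(rz$mean_variation, 0)
})

test_that("mean parameter variation matches E|N(0,1)| * mu", {
  # analytic: eps_l averages |theta (1+mu Z) - theta| / theta = mu |Z|
  zm <- zero_model(1)
  r <- robustness_analysis(zm, 1, 0:3,
                           perturbation_config(mu = 0.2,
                                               n_perturbations = 4000,
                                               seed = 5,
                                               resample_on_invalid = FALSE))
  expected <- 0.2 * sqrt(2 / pi)   # 0.1596
  se <- r$std_variation / sqrt(4000)
  expect_lt(abs(r$mean_variation - expected), 3 * se)
})

test_that("simulation error grows with perturbation strength", {
  g1s <- g1s_model()
  tt <- seq(0, 300, by = 50)
  for (sd in c(2, 9)) {
    ms <- vapply(c(0.05, 0.2), function(mu)
      robustness_analysis(g1s, g1s$exact_params, tt,
                          perturbation_config(mu = mu, n_perturbations = 150,
                                              seed = sd))$mean_sim_error,
      numeric(1))
    expect_lt(ms[1], ms[2])
  }
})

test_that("failed perturbed simulations are counted and excluded", {
  bm <- blowup_model()  # exact 0.4 blows up inside [0, 2] once theta > 0.5
  r <- robustness_analysis(bm, 0.4, seq(0, 2, by = 0.5),
                           perturbation_config(mu = 0.5,
                                               n_perturbations = 100,
                                               seed = 8),
                           max_steps = 2000)
  expect_gt(r$n_failed, 0)
  expect_lte(r$n_failed, 100)
  expect_true(is.finite(r$mean_sim_error))
  # an unperturbed failure aborts
  expect_error(robustness_analysis(bm, 1.5, seq(0, 2, by = 0.5),
                                   perturbation_config(n_perturbations = 2),
                                   max_steps = 2000),
               class = "odeinfer_simulation_error")
})

test_that("failure counts do not decrease with perturbation strength (ERK)", {
  erk <- erk_model()
  tt <- seq(0, 120, by = 20)
  nf <- vapply(c(0.1, 0.2, 0.4), function(mu)
    robustness_analysis(erk, erk$exact_params, tt,
                        perturbation_config(mu = mu, n_perturbations = 60,
                                            seed = 4),
                        max_steps = 20000)$n_failed,
    integer(1))
  expect_true(all(diff(nf) >= 0))
})

test_that("robustness_compare averages reports and ranks by mean error", {
  mk <- function(m, s) structure(list(mean_sim_error = m, std_sim_error = s,
                                      mean_variation = 0.1,
                                      std_variation = 0.01, n_failed = 0L),
                                 class = "robustness_report")
  set.seed(6)
  ms <- runif(10); ss <- runif(10)
  reports <- list(A = lapply(seq_len(10), function(i) mk(ms[i], ss[i])),
                  B = lapply(seq_len(10), function(i) mk(2 * ms[i], ss[i])),
                  C = lapply(seq_len(10), function(i) mk(ms[i], ss[i])))
  out <- robustness_compare(reports)
  expect_equal(out$mean_sim_error[out$criterion == "A"], mean(ms))
  expect_equal(out$rank[out$criterion == "B"], 3L)   # uniformly worse
  expect_equal(out$mean_sim_error[out$criterion == "A"],
               out$mean_sim_error[out$criterion == "C"])
  expect_error(robustness_compare(list(lapply(1:2, mk, s = 0.1))),
               class = "odeinfer_validation_error")
  expect_error(robustness_compare(list(A = list(), B = reports$B)),
               class = "odeinfer_validation_error")
})

test_that("two seeds agree within Monte-Carlo error", {
  g1s <- g1s_model()
  tt <- seq(0, 300, by = 50)
  ra <- robustness_analysis(g1s, g1s$exact_params, tt,
                            perturbation_config(mu = 0.2,
                                                n_perturbations = 400,
                                                seed = 21))
  rb <- robustness_analysis(g1s, g1s$exact_params, tt,
                            perturbation_config(mu = 0.2,
                                                n_perturbations = 400,
                                                seed = 22))
  se <- sqrt(ra$std_sim_error^2 / 400 + rb$std_sim_error^2 / 400)
  expect_lt(abs(ra$mean_sim_error - rb$mean_sim_error), 3 * se)
})
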