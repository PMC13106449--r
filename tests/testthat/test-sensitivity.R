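# Sensitivity machinery: grid structure, Beta-prior analysis, capping.

test_that("the default grid is the 16-cell Se x Sp lattice", {
  g <- grid_spec()
  expect_equal(g$se_values, c(0.80, 0.85, 0.90, 0.95))
  expect_equal(g$sp_values, c(0.65, 0.70, 0.75, 0.80))
  expect_error(grid_spec(se_values = c(0.4, 0.8), sp_values = c(0.5, 0.7)),
               class = "twophaseprev_identifiability_error")
})

test_that("grid medians follow the Rogan-Gladen ordering on fixed data", {
  coh <- simulate_population(census_config(111L, n = 600L,
                                           prevalence = 0.3))
  apparent <- mean(coh$diagnosis == "positive")
  grid <- grid_spec(se_values = c(0.80, 0.90), sp_values = c(0.70, 0.80))
  res <- deterministic_grid(
    coh, latent_model_spec(covariates = NULL), grid,
    quick_mcmc(14L, burn_in = 400L, iterations = 1000L))
  expect_equal(nrow(res), 4L)
  oracle <- purrr::map2_dbl(res$se, res$sp,
                            \(a, b) rogan_gladen(apparent, a, b)$estimate)
  expect_equal(order(res$median), order(oracle))
  # and each cell sits near its closed-form limit
  expect_lt(max(abs(res$median / 1000 - oracle)), 0.05)
})

test_that("a single-cell grid reproduces the equivalent direct fit", {
  coh <- simulate_population(small_sim_config(112L))
  res <- deterministic_grid(coh, latent_model_spec(),
                            grid_spec(0.85, 0.75),
                            quick_mcmc(15L))
  expect_equal(nrow(res), 1L)
  fit <- fit_latent_model(coh, mcmc = quick_mcmc(15L))
  direct <- post_stratify(fit)
  draws <- attr(direct, "overall_draws")
  tol <- 3 * 2 * median_mcse(1000 * draws, 2)
  expect_lt(abs(res$median - direct$median[1]), tol)
})

test_that("Beta prior means are reported as configured", {
  ps <- probabilistic_sensitivity(
    simulate_population(small_sim_config(113L)),
    mcmc = quick_mcmc(16L, burn_in = 300L, iterations = 600L))
  expect_equal(ps$misclass$prior_mean[ps$misclass$parameter == "se"], 0.85)
  expect_equal(ps$misclass$prior_mean[ps$misclass$parameter == "sp"], 0.60)
  expect_error(misclass_spec("beta_prior", se_prior = c(0, 10)),
               class = "twophaseprev_config_error")
})

test_that("point-mass-like priors reproduce the fixed-parameter fit", {
  coh <- simulate_population(small_sim_config(114L))
  ps <- probabilistic_sensitivity(coh, se_prior = c(85000, 15000),
                                  sp_prior = c(60000, 40000),
                                  mcmc = quick_mcmc(17L))
  fixed <- fit_latent_model(
    coh,
    latent_model_spec(misclass = misclass_spec("fixed", se = 0.85,
                                               sp = 0.60)),
    quick_mcmc(18L))
  f <- post_stratify(fixed)
  tol <- 3 * sqrt(median_mcse(attr(f, "overall_draws") * 1000, 2)^2 +
                    median_mcse(attr(ps$prevalence,
                                     "overall_draws") * 1000, 2)^2) + 0.5
  expect_lt(abs(ps$prevalence$median[1] - f$median[1]), tol)
})

test_that("without participant data the Se posterior equals its prior", {
  cfg <- small_sim_config(115L, participation_intercept = -30)
  coh <- simulate_population(cfg)
  expect_warning(
    ps <- probabilistic_sensitivity(coh,
                                    mcmc = quick_mcmc(19L,
                                                      burn_in = 300L,
                                                      iterations = 1000L)),
    "No participants")
  se_row <- ps$misclass[ps$misclass$parameter == "se", ]
  prior_sd <- sqrt(85 * 15 / (100^2 * 101))
  expect_lt(abs(se_row$posterior_mean - 0.85),
            3 * prior_sd / sqrt(2000) * 5)  # conjugate draws, near-iid
})

test_that("capping on a fitted cohort never raises the estimate", {
  coh <- simulate_population(small_sim_config(116L))
  fit <- fit_latent_model(coh, mcmc = quick_mcmc(20L))
  scen <- cap_hr(fit, cap_spec())
  uncapped <- post_stratify(fit)$median[1]
  expect_equal(scen$median[scen$cap == 1], uncapped)
  expect_true(all(diff(scen$median) <= 1e-12))
  expect_true(all(scen$median <= uncapped + 1e-12))
})
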