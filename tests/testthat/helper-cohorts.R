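# Shared fixtures, all generated in code.

# Test-scale strata: same three-arm structure as the reference conditions,
# sized for fast unit tests.
small_strata <- function() {
  stratum_specs(c("LR", "ER", "HR"),
                n_population = c(10000, 292, 112),
                n_sampled = c(600L, 150L, 80L))
}

small_sim_config <- function(seed, ...) {
  sim_config(strata = small_strata(), seed = seed, ...)
}

# One-stratum design where everyone screens positive and (almost) everyone
# participates: the intercept-only model's home ground.
census_config <- function(seed, n = 2000L, prevalence = 0.3,
                          se = 0.85, sp = 0.75,
                          participation_intercept = 10) {
  sim_config(strata = stratum_specs("LR", n_population = 5 * n,
                                    n_sampled = n),
             true_prevalence = c(LR = prevalence),
             screen_cutoff = 0L, se = se, sp = sp,
             participation_intercept = participation_intercept,
             participation_slope_scq = 0,
             seed = seed)
}

quick_mcmc <- function(seed, n_chains = 2L, burn_in = 500L,
                       iterations = 1500L) {
  mcmc_spec(n_chains = n_chains, burn_in = burn_in,
            iterations = iterations, seed = seed)
}

# Hand-built latent_fit stub with constant, known stratum prevalences:
# exercises the post-stratification arithmetic in isolation.
stub_fit <- function(prev_by_stratum, n_population,
                     n_sampled = rep(10L, length(prev_by_stratum)),
                     n_draws = 8L) {
  stopifnot(all(prev_by_stratum * n_sampled ==
                  round(prev_by_stratum * n_sampled)))
  strata <- stratum_specs(names(prev_by_stratum), n_population, n_sampled)
  groups <- tibble::tibble(group = seq_along(prev_by_stratum),
                           stratum = names(prev_by_stratum),
                           sex = "M", grade = 1L,
                           n_sampled = as.integer(n_sampled))
  counts <- matrix(rep(prev_by_stratum * n_sampled, each = n_draws),
                   nrow = n_draws)
  structure(list(chains = list(list(pars = matrix(0, n_draws, 1,
                                                  dimnames = list(NULL,
                                                                  "beta0")),
                                    counts = counts)),
                 groups = groups, strata = strata,
                 intercept_only = TRUE),
            class = "latent_fit")
}

# Monte-Carlo standard error of a posterior median, from the draws
# themselves: 1.25 * sd / sqrt(ESS) (the asymptotic inefficiency of the
# median relative to the mean).
median_mcse <- function(draws, n_chains) {
  m <- matrix(draws, ncol = n_chains)
  ess <- effective_sample_size(m)
  1.25 * stats::sd(draws) / sqrt(ess)
}
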