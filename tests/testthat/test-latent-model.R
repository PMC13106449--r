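# Latent-status model: exactness of the collapsed conditionals, determinism,
# identifiability behaviour, and an independent-engine cross-check.

test_that("a perfect test collapses the latent status onto the diagnosis", {
  cfg <- census_config(91L, n = 400L, prevalence = 0.3, se = 1, sp = 1)
  coh <- simulate_population(cfg)
  fit <- fit_latent_model(
    coh, latent_model_spec(misclass = misclass_spec("fixed", se = 1, sp = 1)),
    quick_mcmc(1L))
  probs <- posterior_case_probabilities(fit)
  y <- coh$diagnosis[match(probs$id, coh$id)] == "positive"
  expect_identical(probs$probability, as.numeric(y))
})

test_that("non-participant probabilities are exchangeable and monotone", {
  # A design with over a thousand participants and a wide score range, so
  # the score slope is decisively positive (posterior z well above 5) and
  # the monotonicity premise — every posterior draw of beta1 > 0 — holds
  # with vanishing failure probability.
  coh <- simulate_population(sim_config(
    strata = stratum_specs("ER", 20000, 4000L),
    true_prevalence = c(ER = 0.35),
    participation_intercept = -1, seed = 92L))
  fit <- fit_latent_model(coh, mcmc = quick_mcmc(2L))
  probs <- posterior_case_probabilities(fit)
  nonp <- dplyr::left_join(probs[!probs$participant, ],
                           coh[c("id", "scq_score")], by = "id")
  # equal SCQ -> identical probability
  dup <- nonp |>
    dplyr::group_by(.data$scq_score) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$probability))
  expect_true(all(dup$k == 1))
  # all beta1 draws positive -> monotone in SCQ
  d <- twophaseprev:::param_draws(fit)
  expect_true(all(d[, "beta1"] > 0))
  ord <- order(nonp$scq_score)
  expect_true(all(diff(nonp$probability[ord]) >= 0))
})

test_that("seeded fits are bit-reproducible and chains are distinct", {
  coh <- simulate_population(small_sim_config(93L))
  f1 <- fit_latent_model(coh, mcmc = quick_mcmc(5L))
  f2 <- fit_latent_model(coh, mcmc = quick_mcmc(5L))
  expect_identical(f1$chains, f2$chains)
  expect_false(identical(f1$chains[[1]]$pars, f1$chains[[2]]$pars))
  f3 <- fit_latent_model(coh, mcmc = quick_mcmc(6L))
  expect_false(identical(f1$chains[[1]]$pars, f3$chains[[1]]$pars))
})

test_that("identifiability is guarded and degenerate inputs refused", {
  coh <- simulate_population(small_sim_config(94L))
  expect_error(misclass_spec("fixed", se = 0.5, sp = 0.5),
               class = "twophaseprev_identifiability_error")
  none <- coh
  none$participated[none$screen_positive] <- FALSE
  none$diagnosis <- NA_character_
  expect_error(fit_latent_model(none, mcmc = quick_mcmc(1L)),
               class = "twophaseprev_degenerate_error")
  neg_only <- coh[!coh$screen_positive, ]
  expect_error(fit_latent_model(neg_only, mcmc = quick_mcmc(1L)),
               "screen-positive")
})

test_that("the corrected-prevalence CrI widens as Se + Sp falls toward 1", {
  coh <- simulate_population(census_config(95L, n = 800L,
                                           prevalence = 0.25))
  width_at <- function(se, sp) {
    fit <- fit_latent_model(
      coh,
      latent_model_spec(covariates = NULL,
                        misclass = misclass_spec("fixed", se = se, sp = sp)),
      quick_mcmc(3L))
    ov <- post_stratify(fit)
    ov$upper[1] - ov$lower[1]
  }
  widths <- c(width_at(0.95, 0.90), width_at(0.85, 0.75),
              width_at(0.75, 0.65))
  expect_true(all(diff(widths) > 0))
})

test_that("the sampler agrees with an independent MCMC engine (rjags)", {
  library(rjags)
  cfg <- census_config(96L, n = 300L, prevalence = 0.3)
  coh <- simulate_population(cfg)
  y <- as.integer(coh$diagnosis == "positive")
  fit <- fit_latent_model(
    coh, latent_model_spec(covariates = NULL),
    mcmc_spec(n_chains = 2, burn_in = 1000, iterations = 4000, seed = 9L))
  d <- twophaseprev:::param_draws(fit)
  mine <- plogis(d[, "beta0"])

  jm <- jags.model(
    textConnection("
      model {
        b0 ~ dnorm(0, 0.16)
        logit(p) <- b0
        for (i in 1:n) {
          z[i] ~ dbern(p)
          y[i] ~ dbern(z[i] * 0.85 + (1 - z[i]) * 0.25)
        }
      }"),
    data = list(y = y, n = length(y)),
    inits = list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 1),
    n.chains = 1, n.adapt = 1000, quiet = TRUE)
  update(jm, 1000, progress.bar = "none")
  js <- coda.samples(jm, "p", 6000, progress.bar = "none")
  theirs <- as.numeric(js[[1]])

  tol <- 3 * sqrt(median_mcse(mine, 2)^2 + median_mcse(theirs, 2)^2) + 0.002
  expect_lt(abs(median(mine) - median(theirs)), tol)
})
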