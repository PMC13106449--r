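# Post-stratification arithmetic (on a fit stub with known constant
# prevalences), the Rogan-Gladen closed form, and subgroup breakdowns.

test_that("post-stratification is the population-weighted convex mix", {
  fit <- stub_fit(c(LR = 0.10, ER = 0.30), n_population = c(9000, 1000))
  res <- post_stratify(fit, scale = "per_1")
  expect_equal(res$median[res$level == "overall"], 0.12)
  expect_equal(sort(res$median[res$level == "stratum"]), c(0.10, 0.30))

  # one stratum: overall equals the stratum value
  one <- post_stratify(stub_fit(c(LR = 0.2), 5000), scale = "per_1")
  expect_equal(one$median[1], 0.2)

  # equal stratum prevalence: overall invariant to the weights
  eq1 <- post_stratify(stub_fit(c(LR = 0.2, HR = 0.2), c(99990, 10)),
                       scale = "per_1")
  eq2 <- post_stratify(stub_fit(c(LR = 0.2, HR = 0.2), c(10, 99990)),
                       scale = "per_1")
  expect_equal(eq1$median[1], 0.2)
  expect_equal(eq2$median[1], 0.2)
})

test_that("every posterior draw satisfies the convex-combination identity", {
  coh <- simulate_population(small_sim_config(101L))
  fit <- fit_latent_model(coh, mcmc = quick_mcmc(11L))
  res <- post_stratify(fit, scale = "per_1")
  d <- twophaseprev:::stratum_prevalence_draws(fit)
  st <- fit$strata[match(colnames(d), fit$strata$stratum), ]
  w <- st$n_population / sum(st$n_population)
  expect_equal(attr(res, "overall_draws"), as.numeric(d %*% w),
               tolerance = 1e-12)
})

test_that("rogan_gladen matches direct arithmetic and flags clamping", {
  expect_equal(rogan_gladen(0.5, 1, 1)$estimate, 0.5)
  expect_equal(rogan_gladen(0.4, 0.85, 0.75)$estimate, 0.25)
  low <- rogan_gladen(0.2, 0.85, 0.75)
  expect_equal(low$estimate, 0)
  expect_true(low$clamped)
  expect_equal(low$raw, -1 / 12, tolerance = 1e-10)
  expect_error(rogan_gladen(0.4, 0.5, 0.5),
               class = "twophaseprev_identifiability_error")
})

test_that("HR capping is exact weighting arithmetic and monotone", {
  fit <- stub_fit(c(LR = 0.10, HR = 1.00), n_population = c(9000, 1000))
  uncapped <- post_stratify(fit, scale = "per_1")$median[1]
  cap1 <- cap_hr(fit, 1.0, scale = "per_1")$median[1]
  cap85 <- cap_hr(fit, 0.85, scale = "per_1")$median[1]
  expect_equal(cap1, uncapped)
  # reduction is exactly 0.15 * N_HR / sum(N)
  expect_equal(uncapped - cap85, 0.15 * 1000 / 10000)
  scen <- cap_hr(fit, cap_spec(), scale = "per_1")
  expect_equal(scen$cap, c(1.00, 0.95, 0.90, 0.85))
  expect_true(all(diff(scen$median) <= 0))
  # no HR stratum -> error
  fit2 <- stub_fit(c(LR = 0.1), 1000)
  expect_error(cap_hr(fit2, 0.9), class = "twophaseprev_config_error")
})

test_that("subgroup breakdowns partition the overall estimate", {
  coh <- simulate_population(small_sim_config(102L))
  fit <- fit_latent_model(coh, mcmc = quick_mcmc(12L))
  overall <- post_stratify(fit)
  for (by in c("sex", "grade")) {
    bd <- sex_grade_breakdown(fit, by)
    # per-draw partition identity implies the medians bracket the overall
    expect_gte(overall$median[1], min(bd$median) - 1e-9)
    expect_lte(overall$median[1], max(bd$median) + 1e-9)
  }
  ratio <- attr(sex_grade_breakdown(fit, "sex"), "adjusted_ratio")
  expect_true(ratio$lower <= ratio$ratio && ratio$ratio <= ratio$upper)
})

test_that("a sex effect in the generator is recovered by the adjusted
           ratio", {
  # The latent model carries no sex term: a child's sex can only reach the
  # subgroup estimates through that child's own diagnosis. With full
  # participation and a perfect measurement the latent status equals the
  # diagnosis equals the truth, so the adjusted ratio must reproduce the
  # empirical true-rate ratio exactly; with an imperfect measurement the
  # sex-blind prior shrinks the ratio toward 1 (see the methods vignette),
  # but a strong generator effect must still be detected.
  base <- list(strata = stratum_specs("LR", 20000, 4000L),
               true_prevalence = c(LR = 0.15),
               screen_cutoff = 0L,
               participation_intercept = 10,
               participation_slope_scq = 0,
               case_or_male = 3, seed = 103L)
  coh <- simulate_population(do.call(sim_config, c(base, se = 1, sp = 1)))
  truth <- coh |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(rate = mean(.data$true_status))
  true_ratio <- truth$rate[truth$sex == "M"] / truth$rate[truth$sex == "F"]
  expect_gt(true_ratio, 1.5)   # the effect is really there
  fit <- fit_latent_model(
    coh, latent_model_spec(misclass = misclass_spec("fixed", se = 1,
                                                    sp = 1)),
    quick_mcmc(13L))
  ratio <- attr(sex_grade_breakdown(fit, "sex"), "adjusted_ratio")
  expect_equal(ratio$ratio, true_ratio, tolerance = 1e-12)

  coh2 <- simulate_population(do.call(sim_config,
                                      c(base, se = 0.95, sp = 0.95)))
  fit2 <- fit_latent_model(
    coh2, latent_model_spec(misclass = misclass_spec("fixed", se = 0.95,
                                                     sp = 0.95)),
    quick_mcmc(13L))
  ratio2 <- attr(sex_grade_breakdown(fit2, "sex"), "adjusted_ratio")
  expect_gt(ratio2$ratio, 1.8)
})

test_that("the screening false-negative correction divides case totals", {
  fit <- stub_fit(c(LR = 0.10, ER = 0.30), n_population = c(9000, 1000))
  plain <- post_stratify(fit, scale = "per_1")
  corr <- post_stratify(fit, scale = "per_1", screening_sensitivity = 0.8)
  expect_equal(corr$median, pmin(plain$median / 0.8, 1))
  expect_error(post_stratify(fit, screening_sensitivity = 0))
})
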