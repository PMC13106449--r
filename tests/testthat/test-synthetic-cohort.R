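# Generator: determinism, marginal laws, and CSV round-trip.

test_that("simulation is deterministic in the seed and sensitive to it", {
  a <- simulate_population(small_sim_config(11L))
  b <- simulate_population(small_sim_config(11L))
  c <- simulate_population(small_sim_config(12L))
  expect_identical(a, b)
  expect_false(identical(a$scq_score, c$scq_score))
})

test_that("with a perfect test and full participation the diagnosed fraction
           recovers stratum prevalence", {
  cfg <- sim_config(
    strata = stratum_specs(c("LR", "ER"), c(20000, 20000),
                           c(10000L, 10000L)),
    true_prevalence = c(LR = 0.05, ER = 0.30),
    screen_cutoff = 0L, se = 1, sp = 1,
    participation_intercept = 30, participation_slope_scq = 0,
    seed = 101L)
  coh <- simulate_population(cfg)
  for (s in c("LR", "ER")) {
    sub <- coh[coh$stratum == s, ]
    p <- cfg$true_prevalence[[s]]
    frac <- mean(sub$diagnosis == "positive")
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / nrow(sub)))
  }
})

test_that("diagnosis error rates match configured Se and Sp", {
  cfg <- census_config(7L, n = 10000L, prevalence = 0.4)
  coh <- simulate_population(cfg)
  obs <- coh[!is.na(coh$diagnosis), ]
  cases <- obs[obs$true_status, ]
  noncases <- obs[!obs$true_status, ]
  se_hat <- mean(cases$diagnosis == "positive")
  fp_hat <- mean(noncases$diagnosis == "positive")
  expect_lt(abs(se_hat - 0.85), 3 * sqrt(0.85 * 0.15 / nrow(cases)))
  expect_lt(abs(fp_hat - 0.25), 3 * sqrt(0.25 * 0.75 / nrow(noncases)))
})

test_that("empirical screen-positive rate matches the mixture-implied rate", {
  # Oracle: scq = clamp(round(N(mu, sd))), so P(scq >= c) = P(N >= c - 0.5)
  # for c in 1..39; mix over case status.
  cfg <- sim_config(strata = stratum_specs("ER", 50000, 20000L),
                    true_prevalence = c(ER = 0.2), seed = 5L)
  coh <- simulate_population(cfg)
  p_case <- 1 - pnorm(10.5, 17, 5)
  p_non <- 1 - pnorm(10.5, 5, 3)
  p_mix <- 0.2 * p_case + 0.8 * p_non
  expect_lt(abs(mean(coh$screen_positive) - p_mix),
            3 * sqrt(p_mix * (1 - p_mix) / nrow(coh)))
})

test_that("zero participation slope leaves participation flat in SCQ", {
  pvals <- purrr::map_dbl(1:100, function(s) {
    coh <- simulate_population(sim_config(
      strata = stratum_specs("ER", 2000, 800L),
      true_prevalence = c(ER = 0.3),
      screen_cutoff = 0L, participation_intercept = 0,
      participation_slope_scq = 0, seed = 3000L + s))
    fit <- fit_participation(coh, "scq_score")
    tidy(fit)$p_value[2]
  })
  expect_gte(sum(pvals > 0.01), 95)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(se = 0.3, sp = 0.6),
               class = "twophaseprev_config_error")
  expect_error(sim_config(true_prevalence = c(LR = 1.2, ER = .3, HR = .9)),
               class = "twophaseprev_config_error")
  expect_error(stratum_specs("LR", 100, 200L),
               class = "twophaseprev_config_error")
  expect_error(stratum_specs("XX", 100, 50L),
               class = "twophaseprev_config_error")
  expect_error(sim_config(screen_cutoff = 40L),
               class = "twophaseprev_config_error")
})

test_that("cohort CSV round-trips identically", {
  coh <- simulate_population(small_sim_config(21L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  rt <- read_cohort(path)
  expect_equal(rt, tibble::as_tibble(coh), ignore_attr = TRUE)
})

test_that("malformed cohort rows fail with the row named", {
  coh <- simulate_population(small_sim_config(22L))
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- coh
  bad$scq_score[3] <- 40L
  expect_error(write_cohort(bad, path), "row 3",
               class = "twophaseprev_parse_error")

  # diagnosis present without participation
  bad2 <- coh
  i <- which(bad2$screen_positive & !bad2$participated)[1]
  bad2$diagnosis[i] <- "positive"
  expect_error(validate_cohort(bad2), "non-participant",
               class = "twophaseprev_parse_error")

  # unknown stratum label straight from a file
  write_cohort(coh, path)
  txt <- readLines(path)
  txt[2] <- sub("^([^,]*),[A-Z]+", "\\1,ZZ", txt[2])
  writeLines(txt, path)
  expect_error(read_cohort(path), "row 1",
               class = "twophaseprev_parse_error")
})
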