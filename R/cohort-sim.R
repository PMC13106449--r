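# Synthetic two-phase cohorts with known ground truth.
#
# The generator emulates the data structure a screen-then-confirm ASD survey
# produces: three risk strata, an SCQ-like 0-39 score whose distribution
# differs by true status, a score-threshold screen, diagnostic-phase
# participation that depends on the score, and an error-prone diagnostic
# outcome with stated sensitivity/specificity.

#' Stratum bookkeeping table
#'
#' @param stratum Character vector of stratum labels, a subset of
#'   `c("LR","ER","HR")` (low-risk mainstream, elevated-risk special schools,
#'   high-risk resource classes).
#' @param n_population Known target population size per stratum (the
#'   post-stratification weights).
#' @param n_sampled Number of screened children per stratum; must not exceed
#'   `n_population`.
#' @return A `stratum_specs` tibble.
#' @export
stratum_specs <- function(stratum, n_population, n_sampled) {
  out <- tibble::tibble(stratum = as.character(stratum),
                        n_population = as.numeric(n_population),
                        n_sampled = as.integer(n_sampled))
  if (anyDuplicated(out$stratum)) abort("Duplicate stratum labels.")
  if (!all(out$stratum %in% stratum_levels)) {
    abort(sprintf("Stratum labels must be among %s.",
                  paste(stratum_levels, collapse = ", ")),
          class = "twophaseprev_config_error")
  }
  if (any(out$n_sampled < 1)) {
    abort("Each stratum must sample at least one child.",
          class = "twophaseprev_config_error")
  }
  if (any(out$n_sampled > out$n_population)) {
    abort("Sampled size exceeds population size in some stratum.",
          class = "twophaseprev_config_error")
  }
  class(out) <- c("stratum_specs", class(out))
  out
}

#' Default study-scale strata
#'
#' Population sizes describe a city-scale school survey (mainstream schools
#' 34,392; special-education schools 292; resource classes 112). Screened
#' counts reflect a ~32.6% screening response in the mainstream stratum
#' (applied to the 8,565 invited) and higher response in the two small
#' special-education strata.
#' @return A `stratum_specs` tibble with rows LR, ER, HR.
#' @export
default_stratum_specs <- function() {
  stratum_specs(c("LR", "ER", "HR"),
                n_population = c(34392, 292, 112),
                n_sampled = c(2792L, 190L, 90L))
}

#' Simulation configuration
#'
#' Defines the data-generating process for [simulate_population()]. Defaults
#' are the package's reference study conditions (see the methods vignette).
#'
#' @param strata A [stratum_specs()] tibble.
#' @param true_prevalence Named numeric vector of true ASD prevalence per
#'   stratum (names matching `strata$stratum`).
#' @param scq_case,scq_noncase Length-2 numeric `c(mean, sd)` of the latent
#'   normal from which SCQ totals are drawn (then rounded and truncated to
#'   0-39) for true cases / non-cases.
#' @param screen_cutoff Screen-positive threshold on the SCQ total
#'   (default 11; score >= cutoff is positive).
#' @param se,sp Sensitivity and specificity of the error-prone diagnostic
#'   measurement applied to participants; must satisfy `se + sp > 1`.
#' @param participation_intercept,participation_slope_scq Logistic-model
#'   coefficients (log-odds scale) for diagnostic-phase participation among
#'   screen-positives: `logit(P(participate)) = intercept + slope * SCQ`.
#' @param male_fraction Probability a child is male.
#' @param case_or_male Odds ratio of true ASD for males vs females within each
#'   stratum (1 = sex-independent). Stratum prevalence is preserved exactly:
#'   sex-specific probabilities are solved so their mixture equals
#'   `true_prevalence`.
#' @param grade_probs Length-3 probabilities of grades 1-3.
#' @param seed Integer seed; the single source of randomness.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(strata = default_stratum_specs(),
                       true_prevalence = c(LR = 0.017, ER = 0.30, HR = 0.95),
                       scq_case = c(17, 5),
                       scq_noncase = c(5, 3),
                       screen_cutoff = 11L,
                       se = 0.85, sp = 0.75,
                       participation_intercept = -3.2,
                       participation_slope_scq = 0.15,
                       male_fraction = 0.517,
                       case_or_male = 1,
                       grade_probs = c(1, 1, 1) / 3,
                       seed = 20230101L) {
  if (!inherits(strata, "stratum_specs")) {
    strata <- stratum_specs(strata$stratum, strata$n_population,
                            strata$n_sampled)
  }
  if (nrow(strata) == 0) {
    abort("At least one stratum is required.",
          class = "twophaseprev_config_error")
  }
  if (!all(strata$stratum %in% names(true_prevalence))) {
    abort("`true_prevalence` must name every stratum.",
          class = "twophaseprev_config_error")
  }
  check_prob(unname(true_prevalence), "true_prevalence")
  check_prob(se, "se"); check_prob(sp, "sp")
  if (se + sp <= 1) {
    abort("se + sp must exceed 1 (informative diagnostic measurement).",
          class = "twophaseprev_config_error")
  }
  check_prob(male_fraction, "male_fraction")
  if (length(grade_probs) != 3 || abs(sum(grade_probs) - 1) > 1e-8) {
    abort("`grade_probs` must be 3 probabilities summing to 1.",
          class = "twophaseprev_config_error")
  }
  cutoff <- check_count(screen_cutoff, "screen_cutoff")
  if (cutoff < 0 || cutoff > 39) {
    abort("`screen_cutoff` must lie in [0, 39].",
          class = "twophaseprev_config_error")
  }
  if (!is.numeric(case_or_male) || case_or_male <= 0) {
    abort("`case_or_male` must be a positive odds ratio.",
          class = "twophaseprev_config_error")
  }
  structure(list(
    strata = strata,
    true_prevalence = true_prevalence[strata$stratum],
    scq_case = scq_case, scq_noncase = scq_noncase,
    screen_cutoff = cutoff, se = se, sp = sp,
    participation_intercept = participation_intercept,
    participation_slope_scq = participation_slope_scq,
    male_fraction = male_fraction, case_or_male = case_or_male,
    grade_probs = grade_probs,
    seed = check_count(seed, "seed")
  ), class = "sim_config")
}

# Solve sex-specific case probabilities (pm, pf) such that
# fm*pm + (1-fm)*pf = p and odds(pm) = or * odds(pf).
sex_split_probs <- function(p, fm, or) {
  if (or == 1 || p %in% c(0, 1)) return(c(m = p, f = p))
  f <- function(pf) {
    pm <- plogis(qlogis(pf) + log(or))
    fm * pm + (1 - fm) * pf - p
  }
  pf <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(m = plogis(qlogis(pf) + log(or)), f = pf)
}

#' Simulate a two-phase cohort
#'
#' Draws, per stratum, `n_sampled` children with latent true status
#' `Bernoulli(true_prevalence)`; an SCQ total from the class-specific
#' discretized truncated normal; screen status by the cutoff; diagnostic-phase
#' participation `Bernoulli(plogis(intercept + slope * SCQ))` among
#' screen-positives; and, among participants, a diagnostic outcome
#' `Bernoulli(z * se + (1 - z) * (1 - sp))`. Fully reproducible given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A cohort tibble with columns `id`, `stratum`, `grade`, `sex`,
#'   `scq_score`, `screen_positive`, `participated` (NA for
#'   screen-negatives), `diagnosis` (`"positive"`/`"negative"`/NA) and
#'   `true_status` (logical ground truth; synthetic cohorts only). The screen
#'   cutoff and stratum table travel along as attributes `screen_cutoff` and
#'   `strata`.
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config.")
  set.seed(config$seed)
  strata <- config$strata
  n <- sum(strata$n_sampled)
  stratum <- rep(strata$stratum, strata$n_sampled)
  sex <- ifelse(runif(n) < config$male_fraction, "M", "F")
  grade <- sample.int(3L, n, replace = TRUE, prob = config$grade_probs)
  p_case <- numeric(n)
  for (s in strata$stratum) {
    idx <- stratum == s
    pr <- sex_split_probs(unname(config$true_prevalence[[s]]),
                          config$male_fraction, config$case_or_male)
    p_case[idx] <- ifelse(sex[idx] == "M", pr[["m"]], pr[["f"]])
  }
  true_status <- rbinom(n, 1L, p_case) == 1L
  draw_scq <- function(k, pars) {
    if (k == 0) return(integer(0))
    pmin(39L, pmax(0L, as.integer(round(rnorm(k, pars[1], pars[2])))))
  }
  scq <- integer(n)
  scq[true_status] <- draw_scq(sum(true_status), config$scq_case)
  scq[!true_status] <- draw_scq(sum(!true_status), config$scq_noncase)
  screen_positive <- scq >= config$screen_cutoff
  participated <- rep(NA, n)
  sp_idx <- which(screen_positive)
  p_part <- plogis(config$participation_intercept +
                     config$participation_slope_scq * scq[sp_idx])
  participated[sp_idx] <- rbinom(length(sp_idx), 1L, p_part) == 1L
  diagnosis <- rep(NA_character_, n)
  obs <- which(screen_positive & !is.na(participated) & participated)
  p_pos <- ifelse(true_status[obs], config$se, 1 - config$sp)
  diagnosis[obs] <- ifelse(rbinom(length(obs), 1L, p_pos) == 1L,
                           "positive", "negative")
  out <- tibble::tibble(
    id = sprintf("C%05d", seq_len(n)),
    stratum = stratum,
    grade = as.integer(grade),
    sex = sex,
    scq_score = scq,
    screen_positive = screen_positive,
    participated = as.logical(participated),
    diagnosis = diagnosis,
    true_status = true_status
  )
  attr(out, "screen_cutoff") <- config$screen_cutoff
  attr(out, "strata") <- strata
  out
}

#' Simulate a cohort whose latent structure matches the analysis model
#'
#' Companion generator for calibration studies. Where [simulate_population()]
#' draws true status first and SCQ score given status, this generator draws
#' the SCQ score first (stratum-specific discretized truncated normals) and
#' then true status from the analysis model's own logistic law,
#' `P(z = 1 | scq) = plogis(beta0 + beta1 * scq)` on the raw score scale —
#' identical across strata, which then differ only through their score
#' distributions. Under this process the latent prevalence model is exactly
#' correctly specified, so posterior coverage of the generator's `beta0`,
#' `beta1` and of the realized prevalence can be checked directly.
#'
#' Screening, participation and the error-prone diagnosis are generated as
#' in [simulate_population()].
#'
#' @param strata A [stratum_specs()] tibble.
#' @param scq_means,scq_sds Per-stratum mean/SD (named or in stratum order)
#'   of the latent normal behind the SCQ total.
#' @param beta0,beta1 Logistic coefficients of true status on the raw SCQ
#'   score.
#' @param screen_cutoff,se,sp,participation_intercept,participation_slope_scq
#'   As in [sim_config()].
#' @param male_fraction,grade_probs As in [sim_config()].
#' @param seed Integer seed.
#' @return A cohort tibble as from [simulate_population()], with attributes
#'   `screen_cutoff`, `strata`, and `generator` (the parameter list).
#' @export
simulate_logistic_cohort <- function(strata = default_stratum_specs(),
                                     scq_means = c(LR = 5, ER = 9, HR = 16),
                                     scq_sds = c(LR = 4, ER = 5, HR = 6),
                                     beta0 = -7, beta1 = 0.35,
                                     screen_cutoff = 11L,
                                     se = 0.85, sp = 0.75,
                                     participation_intercept = -3.2,
                                     participation_slope_scq = 0.15,
                                     male_fraction = 0.517,
                                     grade_probs = c(1, 1, 1) / 3,
                                     seed = 20230101L) {
  if (!inherits(strata, "stratum_specs")) {
    strata <- stratum_specs(strata$stratum, strata$n_population,
                            strata$n_sampled)
  }
  check_prob(se, "se"); check_prob(sp, "sp")
  if (se + sp <= 1) {
    abort("se + sp must exceed 1.", class = "twophaseprev_config_error")
  }
  if (is.null(names(scq_means))) names(scq_means) <- strata$stratum
  if (is.null(names(scq_sds))) names(scq_sds) <- strata$stratum
  set.seed(check_count(seed, "seed"))
  n <- sum(strata$n_sampled)
  stratum <- rep(strata$stratum, strata$n_sampled)
  sex <- ifelse(runif(n) < male_fraction, "M", "F")
  grade <- as.integer(sample.int(3L, n, replace = TRUE, prob = grade_probs))
  scq <- pmin(39L, pmax(0L, as.integer(round(
    rnorm(n, scq_means[stratum], scq_sds[stratum])))))
  true_status <- rbinom(n, 1L, plogis(beta0 + beta1 * scq)) == 1L
  screen_positive <- scq >= screen_cutoff
  participated <- rep(NA, n)
  sp_idx <- which(screen_positive)
  participated[sp_idx] <- rbinom(
    length(sp_idx), 1L,
    plogis(participation_intercept +
             participation_slope_scq * scq[sp_idx])) == 1L
  diagnosis <- rep(NA_character_, n)
  obs <- which(screen_positive & !is.na(participated) & participated)
  diagnosis[obs] <- ifelse(
    rbinom(length(obs), 1L,
           ifelse(true_status[obs], se, 1 - sp)) == 1L,
    "positive", "negative")
  out <- tibble::tibble(
    id = sprintf("C%05d", seq_len(n)), stratum = stratum,
    grade = grade, sex = sex, scq_score = scq,
    screen_positive = screen_positive,
    participated = as.logical(participated),
    diagnosis = diagnosis, true_status = true_status)
  attr(out, "screen_cutoff") <- as.integer(screen_cutoff)
  attr(out, "strata") <- strata
  attr(out, "generator") <- list(beta0 = beta0, beta1 = beta1, se = se,
                                 sp = sp)
  out
}
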