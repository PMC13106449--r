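# Bayesian latent-status prevalence model.
#
# True case status z_i of each screen-positive child is latent:
#   z_i ~ Bernoulli(p_i),  logit(p_i) = beta0 + beta1 * scq_i (centered)
# Participants' diagnostic outcomes are error-prone measurements of z_i:
#   y_i | z_i ~ Bernoulli(z_i * Se + (1 - z_i) * (1 - Sp))
# Non-participants contribute no measurement; their z_i is imputed from the
# prior-predictive given beta, which is how differential participation is
# adjusted for (the SCQ score drives both participation and p_i).
#
# Sampler: partially collapsed Gibbs. The latent z is integrated out of the
# beta update analytically — given (beta, Se, Sp) a participant's outcome is
# marginally Bernoulli(q_i) with q_i = p_i Se + (1 - p_i)(1 - Sp), and
# non-participants drop out of the likelihood entirely — so beta moves
# against the marginal posterior and the chain has no slow random-walk
# coupling with the imputation. Per iteration, in this fixed order:
#   (1) beta: componentwise random-walk Metropolis (beta0 then beta1, three
#       sweeps per scan) on the marginal measurement likelihood plus
#       independent normal priors; each proposal SD adapted toward ~44%
#       acceptance during burn-in only, frozen afterwards;
#   (2) z: exact full-conditional Bernoulli draw — participants weigh the
#       measurement likelihood, non-participants draw from p_i alone;
#   (3) Se, Sp (beta_prior mode only): exact conjugate Beta draws from the
#       binomial (z, y) counts among participants.
# Drawing z after the marginal beta update and (Se, Sp) from the z-augmented
# conditional is the standard valid ordering for this collapse. Draws are
# recorded at the end of the scan. Chains run sequentially with seeds derived
# from the single MCMC seed (see split_seed), so runs are bit-reproducible.

#' Misclassification specification
#'
#' Sensitivity/specificity of the error-prone diagnostic measurement, either
#' fixed (primary analysis) or given informative Beta priors (probabilistic
#' sensitivity analysis).
#'
#' @param mode `"fixed"` or `"beta_prior"`.
#' @param se,sp Fixed values (fixed mode); must satisfy `se + sp > 1`.
#' @param se_prior,sp_prior Length-2 `c(a, b)` Beta parameters (beta_prior
#'   mode); defaults Beta(85, 15) and Beta(60, 40).
#' @return A `misclass_spec` list.
#' @export
misclass_spec <- function(mode = c("fixed", "beta_prior"),
                          se = 0.85, sp = 0.75,
                          se_prior = c(85, 15), sp_prior = c(60, 40)) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    check_prob(se, "se"); check_prob(sp, "sp")
    if (se + sp <= 1) {
      abort("Fixed se + sp must exceed 1 (identifiability).",
            class = "twophaseprev_identifiability_error")
    }
  } else {
    for (pr in list(se_prior = se_prior, sp_prior = sp_prior)) {
      if (length(pr) != 2 || any(!is.finite(pr)) || any(pr <= 0)) {
        abort("Beta prior parameters must be two positive numbers.",
              class = "twophaseprev_config_error")
      }
    }
  }
  structure(list(mode = mode, se = se, sp = sp,
                 se_prior = se_prior, sp_prior = sp_prior),
            class = "misclass_spec")
}

#' MCMC settings
#'
#' @param n_chains Number of chains (>= 2 so split-R-hat is defined).
#' @param burn_in Discarded warm-up iterations per chain.
#' @param iterations Retained post-burn-in iterations per chain (before
#'   thinning).
#' @param thinning Keep every `thinning`-th post-burn-in draw.
#' @param seed Integer seed driving all chains.
#' @return An `mcmc_spec` list. Defaults: 3 chains, 5,000 burn-in, 10,000
#'   post-burn-in iterations, no thinning.
#' @export
mcmc_spec <- function(n_chains = 3L, burn_in = 5000L, iterations = 10000L,
                      thinning = 1L, seed = 1L) {
  n_chains <- check_count(n_chains, "n_chains", positive = TRUE)
  if (n_chains < 2) {
    abort("At least 2 chains are required for convergence diagnostics.",
          class = "twophaseprev_config_error")
  }
  structure(list(n_chains = n_chains,
                 burn_in = check_count(burn_in, "burn_in", positive = TRUE),
                 iterations = check_count(iterations, "iterations",
                                          positive = TRUE),
                 thinning = check_count(thinning, "thinning",
                                        positive = TRUE),
                 seed = check_count(seed, "seed")),
            class = "mcmc_spec")
}

#' Latent model specification
#'
#' @param covariates Covariates of the latent linear predictor: the default
#'   `"scq_score"` (centered at the screen-positive sample mean before
#'   entering the model), or `NULL` for an intercept-only model.
#' @param prior_mean,prior_sd Mean and SD of the independent normal priors on
#'   the coefficients (centered-covariate scale). Default Normal(0, 2.5^2),
#'   weakly informative for logistic models.
#' @param misclass A [misclass_spec()].
#' @return A `latent_model_spec` list.
#' @export
latent_model_spec <- function(covariates = "scq_score",
                              prior_mean = 0, prior_sd = 2.5,
                              misclass = misclass_spec()) {
  if (!is.null(covariates) && !identical(covariates, "scq_score")) {
    abort("`covariates` must be \"scq_score\" or NULL (intercept-only).")
  }
  if (!is.numeric(prior_sd) || any(prior_sd <= 0)) {
    abort("`prior_sd` must be positive.",
          class = "twophaseprev_config_error")
  }
  if (!inherits(misclass, "misclass_spec")) {
    abort("`misclass` must be a misclass_spec.")
  }
  structure(list(covariates = covariates, prior_mean = prior_mean,
                 prior_sd = prior_sd, misclass = misclass),
            class = "latent_model_spec")
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Fit the latent-status prevalence model
#'
#' Runs the data-augmented Gibbs sampler described above on the
#' screen-positive children of a cohort. Screen-negative children carry no
#' latent variable (they contribute zero cases in the primary analysis) but
#' remain in the post-stratification denominators.
#'
#' @param records A validated cohort tibble containing at least one
#'   screen-positive child. Participants must have observed diagnoses.
#' @param model A [latent_model_spec()].
#' @param mcmc An [mcmc_spec()].
#' @param strata A [stratum_specs()] table; defaults to the cohort attribute.
#' @return A `latent_fit` object holding per-chain coefficient draws (and
#'   Se/Sp draws in beta_prior mode), per-chain per-draw latent case counts
#'   by stratum-sex-grade cell, per-participant posterior case
#'   probabilities, and the specs used. Feed it to [post_stratify()],
#'   [posterior_case_probabilities()], [diagnose_fit()], [tidy()].
#' @export
fit_latent_model <- function(records, model = latent_model_spec(),
                             mcmc = mcmc_spec(),
                             strata = attr(records, "strata")) {
  validate_cohort(records)
  if (!inherits(model, "latent_model_spec")) {
    abort("`model` must be a latent_model_spec.")
  }
  if (!inherits(mcmc, "mcmc_spec")) abort("`mcmc` must be an mcmc_spec.")
  mis <- model$misclass
  sp_rec <- dplyr::filter(records, .data$screen_positive)
  if (nrow(sp_rec) == 0) abort("No screen-positive children in `records`.")
  participant <- sp_rec$participated
  if (!any(participant)) {
    if (mis$mode == "fixed") {
      abort("No participants: the fixed-Se/Sp model is not estimable.",
            class = "twophaseprev_degenerate_error")
    }
    warn(paste("No participants: posterior for Se/Sp equals the prior and",
               "prevalence is prior-driven."))
  }
  y <- ifelse(participant, as.integer(sp_rec$diagnosis == "positive"), NA)

  # Stratum-sex-grade cells over ALL sampled children: denominators include
  # screen-negatives (they count zero cases).
  groups <- records |>
    dplyr::count(.data$stratum, .data$sex, .data$grade,
                 name = "n_sampled") |>
    dplyr::arrange(.data$stratum, .data$sex, .data$grade) |>
    dplyr::mutate(group = dplyr::row_number(), .before = 1)
  grp <- dplyr::left_join(
    sp_rec[c("stratum", "sex", "grade")], groups,
    by = c("stratum", "sex", "grade"))$group
  G <- nrow(groups)

  intercept_only <- is.null(model$covariates)
  center <- mean(sp_rec$scq_score)
  x <- if (intercept_only) rep(0, nrow(sp_rec)) else sp_rec$scq_score - center
  npar <- if (intercept_only) 1L else 2L
  pm <- rep_len(model$prior_mean, npar)
  psd <- rep_len(model$prior_sd, npar)

  n_keep <- mcmc$iterations %/% mcmc$thinning
  idx_part <- which(participant)
  idx_nonp <- which(!participant)
  y_part <- y[idx_part]
  x_part <- x[idx_part]
  random_sesp <- mis$mode == "beta_prior"

  run_chain <- function(chain) {
    set.seed(split_seed(mcmc$seed, chain))
    beta <- rep(0, npar)
    se <- if (random_sesp) mis$se_prior[1] / sum(mis$se_prior) else mis$se
    sp <- if (random_sesp) mis$sp_prior[1] / sum(mis$sp_prior) else mis$sp
    z <- integer(nrow(sp_rec))
    z[idx_part] <- y_part
    z[idx_nonp] <- rbinom(length(idx_nonp), 1L, 0.5)
    step <- rep(0.3, npar)
    acc <- 0; acc_window <- numeric(npar)
    pars <- matrix(NA_real_, n_keep,
                   npar + if (random_sesp) 2L else 0L)
    colnames(pars) <- c(c("beta0", "beta1")[seq_len(npar)],
                        if (random_sesp) c("se", "sp"))
    counts <- matrix(NA_integer_, n_keep, G)
    pz_sum <- numeric(length(idx_part))
    # Marginal (z-collapsed) log posterior of beta given (se, sp):
    # participants only; non-participants integrate to 1.
    logpost <- function(b) {
      eta <- b[1] + if (npar == 2) b[2] * x_part else 0
      p <- plogis(eta)
      q <- p * se + (1 - p) * (1 - sp)
      sum(log(pmax(ifelse(y_part == 1L, q, 1 - q), 1e-300))) -
        sum((b - pm)^2 / (2 * psd^2))
    }
    lp <- logpost(beta)
    total <- mcmc$burn_in + mcmc$iterations
    kept <- 0L
    # Three Metropolis sweeps per scan: the marginal-likelihood evaluation is
    # over participants only, so extra sweeps are cheap relative to the
    # z imputation and cut the beta autocorrelation accordingly.
    n_sweeps <- 3L
    for (it in seq_len(total)) {
      for (sweep in seq_len(n_sweeps)) {
        for (j in seq_len(npar)) {
          prop <- beta
          prop[j] <- prop[j] + rnorm(1, 0, step[j])
          lp_prop <- logpost(prop)
          if (log(runif(1)) < lp_prop - lp) {
            beta <- prop; lp <- lp_prop
            acc <- acc + 1 / (npar * n_sweeps)
            acc_window[j] <- acc_window[j] + 1 / n_sweeps
          }
        }
      }
      if (it <= mcmc$burn_in && it %% 50L == 0L) {
        step <- step * exp(acc_window / 50 - 0.44)
        acc_window[] <- 0
      }
      eta <- rep_len(beta[1], length(x))
      if (npar == 2) eta <- eta + beta[2] * x
      if (!all(is.finite(eta))) {
        abort("Non-finite linear predictor during sampling.")
      }
      p <- plogis(eta)
      if (length(idx_part)) {
        pp <- p[idx_part]
        w1 <- pp * ifelse(y_part == 1L, se, 1 - se)
        w0 <- (1 - pp) * ifelse(y_part == 1L, 1 - sp, sp)
        pz <- ifelse(w1 + w0 > 0, w1 / (w1 + w0), pp)
        z[idx_part] <- rbinom(length(idx_part), 1L, pz)
      }
      if (length(idx_nonp)) {
        z[idx_nonp] <- rbinom(length(idx_nonp), 1L, p[idx_nonp])
      }
      if (random_sesp) {
        if (length(idx_part)) {
          zp <- z[idx_part]
          n11 <- sum(zp == 1L & y_part == 1L)
          n10 <- sum(zp == 1L & y_part == 0L)
          n00 <- sum(zp == 0L & y_part == 0L)
          n01 <- sum(zp == 0L & y_part == 1L)
          se <- stats::rbeta(1, mis$se_prior[1] + n11, mis$se_prior[2] + n10)
          sp <- stats::rbeta(1, mis$sp_prior[1] + n00, mis$sp_prior[2] + n01)
        } else {
          se <- stats::rbeta(1, mis$se_prior[1], mis$se_prior[2])
          sp <- stats::rbeta(1, mis$sp_prior[1], mis$sp_prior[2])
        }
        lp <- logpost(beta)  # (se, sp) changed; refresh cached target
      }
      if (it > mcmc$burn_in &&
          (it - mcmc$burn_in) %% mcmc$thinning == 0L) {
        kept <- kept + 1L
        pars[kept, seq_len(npar)] <- beta
        if (random_sesp) pars[kept, npar + 1:2] <- c(se, sp)
        counts[kept, ] <- tabulate(grp[z == 1L], nbins = G)
        pz_sum <- pz_sum + z[idx_part]
      }
    }
    list(pars = pars[seq_len(kept), , drop = FALSE],
         counts = counts[seq_len(kept), , drop = FALSE],
         pz_sum = pz_sum, kept = kept,
         acceptance = acc / total, step = step)
  }

  chains <- purrr::map(seq_len(mcmc$n_chains), run_chain)
  total_kept <- sum(purrr::map_int(chains, "kept"))
  pz_part <- Reduce(`+`, purrr::map(chains, "pz_sum")) / total_kept

  structure(list(
    chains = purrr::map(chains, \(ch) ch[c("pars", "counts")]),
    acceptance = purrr::map_dbl(chains, "acceptance"),
    groups = groups,
    strata = strata,
    records_sp = tibble::tibble(
      id = sp_rec$id, stratum = sp_rec$stratum, sex = sp_rec$sex,
      grade = sp_rec$grade, scq_score = sp_rec$scq_score, x = x,
      participant = participant, y = y, group = grp),
    pz_participants = tibble::tibble(id = sp_rec$id[idx_part],
                                     probability = pz_part),
    center = center, intercept_only = intercept_only,
    model = model, mcmc = mcmc,
    n_screen_positive = nrow(sp_rec),
    n_participants = length(idx_part)
  ), class = "latent_fit")
}

#' @export
print.latent_fit <- function(x, ...) {
  cat(sprintf(
    "Latent-status prevalence model: %d screen-positives (%d participants)\n",
    x$n_screen_positive, x$n_participants))
  cat(sprintf("%d chains x %d kept draws; Se/Sp %s\n",
              x$mcmc$n_chains, nrow(x$chains[[1]]$pars),
              if (x$model$misclass$mode == "fixed")
                sprintf("fixed at %.2f/%.2f", x$model$misclass$se,
                        x$model$misclass$sp)
              else "with Beta priors"))
  print(tidy(x), ...)
  invisible(x)
}

# Stacked parameter draws across chains (matrix, named columns).
param_draws <- function(fit) {
  do.call(rbind, purrr::map(fit$chains, "pars"))
}

#' @rdname fit_latent_model
#' @param x A `latent_fit`.
#' @param ... Unused.
#' @method tidy latent_fit
#' @export
tidy.latent_fit <- function(x, ...) {
  d <- param_draws(x)
  out <- tibble::tibble(
    term = colnames(d),
    estimate = apply(d, 2, median),
    conf_low = apply(d, 2, quantile, 0.025),
    conf_high = apply(d, 2, quantile, 0.975))
  # Intercept back on the raw-SCQ scale for reporting alongside the
  # centered-scale estimate.
  if (!x$intercept_only) {
    raw0 <- d[, "beta0"] - d[, "beta1"] * x$center
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "beta0_raw_scale", estimate = median(raw0),
      conf_low = quantile(raw0, 0.025), conf_high = quantile(raw0, 0.975)))
  }
  out
}

#' @rdname fit_latent_model
#' @method glance latent_fit
#' @export
glance.latent_fit <- function(x, ...) {
  tibble::tibble(n_screen_positive = x$n_screen_positive,
                 n_participants = x$n_participants,
                 n_chains = x$mcmc$n_chains,
                 draws_per_chain = nrow(x$chains[[1]]$pars),
                 mean_acceptance = mean(x$acceptance),
                 misclass_mode = x$model$misclass$mode)
}
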