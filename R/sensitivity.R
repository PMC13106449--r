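# Robustness machinery: deterministic Se x Sp grids, probabilistic
# (Beta-prior) sensitivity analysis, and high-risk-stratum capping.

#' Deterministic sensitivity grid specification
#'
#' @param se_values,sp_values Ordered probability vectors; every (se, sp)
#'   pair must satisfy `se + sp > 1`. Defaults give the 16-cell grid
#'   Se in \{0.80, 0.85, 0.90, 0.95\} x Sp in \{0.65, 0.70, 0.75, 0.80\}.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(se_values = c(0.80, 0.85, 0.90, 0.95),
                      sp_values = c(0.65, 0.70, 0.75, 0.80)) {
  check_prob(se_values, "se_values", open = TRUE)
  check_prob(sp_values, "sp_values", open = TRUE)
  if (min(se_values) + min(sp_values) <= 1) {
    abort("Every (se, sp) grid cell must satisfy se + sp > 1.",
          class = "twophaseprev_identifiability_error")
  }
  structure(list(se_values = sort(se_values), sp_values = sort(sp_values)),
            class = "grid_spec")
}

#' High-risk-stratum cap specification
#'
#' @param hr_caps Upper bounds, in (0, 1], applied to the HR stratum's
#'   posterior prevalence. Default `c(1.00, 0.95, 0.90, 0.85)`.
#' @return A `cap_spec` list.
#' @export
cap_spec <- function(hr_caps = c(1.00, 0.95, 0.90, 0.85)) {
  check_prob(hr_caps, "hr_caps")
  if (any(hr_caps == 0)) {
    abort("Caps must lie in (0, 1].", class = "twophaseprev_config_error")
  }
  structure(list(hr_caps = hr_caps), class = "cap_spec")
}

#' Deterministic sensitivity analysis over an Se x Sp grid
#'
#' Refits the latent model once per grid cell with Se/Sp fixed at the cell
#' values. Each cell reuses the primary MCMC seed plus a fixed per-cell
#' offset, so cells are reproducible and comparable.
#'
#' @param records A validated cohort tibble.
#' @param base_model A [latent_model_spec()]; its misclassification spec is
#'   replaced cell by cell.
#' @param grid A [grid_spec()].
#' @param mcmc An [mcmc_spec()].
#' @param strata A [stratum_specs()] table; defaults to the cohort attribute.
#' @return A tidy tibble, one row per (se, sp) cell: `se`, `sp`, `median`,
#'   `lower`, `upper` (overall post-stratified prevalence, per 1,000).
#' @export
deterministic_grid <- function(records, base_model = latent_model_spec(),
                               grid = grid_spec(), mcmc = mcmc_spec(),
                               strata = attr(records, "strata")) {
  if (!inherits(grid, "grid_spec")) abort("`grid` must be a grid_spec.")
  cells <- tidyr::expand_grid(se = grid$se_values, sp = grid$sp_values)
  purrr::pmap_dfr(
    dplyr::mutate(cells, cell = dplyr::row_number()),
    function(se, sp, cell) {
      model <- base_model
      model$misclass <- misclass_spec("fixed", se = se, sp = sp)
      cell_mcmc <- mcmc
      cell_mcmc$seed <- split_seed(mcmc$seed, 1000 + cell)
      fit <- fit_latent_model(records, model, cell_mcmc, strata)
      res <- post_stratify(fit, strata)
      ov <- res[res$level == "overall", ]
      tibble::tibble(se = se, sp = sp, median = ov$median,
                     lower = ov$lower, upper = ov$upper)
    })
}

#' Probabilistic sensitivity analysis with Beta priors on Se and Sp
#'
#' Fits the latent model with Se and Sp treated as uncertain parameters with
#' informative Beta priors (defaults Beta(85, 15) and Beta(60, 40), prior
#' means 0.85 and 0.60). Se/Sp are drawn by exact conjugate Gibbs updates
#' from the (z, y) counts among participants.
#'
#' @param records A validated cohort tibble.
#' @param base_model A [latent_model_spec()]; its misclassification spec is
#'   replaced by the Beta priors.
#' @param se_prior,sp_prior Length-2 `c(a, b)` Beta parameters.
#' @param mcmc An [mcmc_spec()].
#' @param strata A [stratum_specs()] table; defaults to the cohort attribute.
#' @return A list: `prevalence` (a [post_stratify()] result), `misclass`
#'   (posterior summaries of Se and Sp), and `fit` (the underlying
#'   `latent_fit`).
#' @export
probabilistic_sensitivity <- function(records,
                                      base_model = latent_model_spec(),
                                      se_prior = c(85, 15),
                                      sp_prior = c(60, 40),
                                      mcmc = mcmc_spec(),
                                      strata = attr(records, "strata")) {
  model <- base_model
  model$misclass <- misclass_spec("beta_prior", se_prior = se_prior,
                                  sp_prior = sp_prior)
  fit <- fit_latent_model(records, model, mcmc, strata)
  d <- param_draws(fit)
  mis <- purrr::map_dfr(c("se", "sp"), \(p) tibble::tibble(
    parameter = p,
    prior_mean = model$misclass[[paste0(p, "_prior")]][1] /
      sum(model$misclass[[paste0(p, "_prior")]]),
    posterior_mean = mean(d[, p]),
    posterior_median = median(d[, p]),
    lower = quantile(d[, p], 0.025, names = FALSE),
    upper = quantile(d[, p], 0.975, names = FALSE)))
  list(prevalence = post_stratify(fit, strata), misclass = mis, fit = fit)
}

#' Cap the high-risk stratum's posterior prevalence
#'
#' Per draw, replaces the HR stratum prevalence by `min(value, cap)` before
#' post-stratification; other strata are untouched. With `cap = 1` the
#' result is identical to the uncapped estimate.
#'
#' @param fit A [fit_latent_model()] result whose cohort includes an HR
#'   stratum.
#' @param cap A single cap in (0, 1], or a [cap_spec()] to evaluate the
#'   whole default scenario set \{1.00, 0.95, 0.90, 0.85\}.
#' @param strata A [stratum_specs()] table; defaults to the fit's.
#' @param scale `"per_1000"` (default) or `"per_1"`.
#' @return For a single cap, a [post_stratify()] result. For a `cap_spec`, a
#'   tidy tibble with one row per cap: `cap`, `median`, `lower`, `upper`
#'   (overall prevalence).
#' @export
cap_hr <- function(fit, cap = cap_spec(), strata = fit$strata,
                   scale = c("per_1000", "per_1")) {
  scale <- match.arg(scale)
  if (!"HR" %in% fit$groups$stratum) {
    abort("No HR stratum in the fitted cohort.",
          class = "twophaseprev_config_error")
  }
  if (inherits(cap, "cap_spec")) {
    return(purrr::map_dfr(cap$hr_caps, function(cp) {
      res <- post_stratify(fit, strata, scale, hr_cap = cp)
      ov <- res[res$level == "overall", ]
      tibble::tibble(cap = cp, median = ov$median, lower = ov$lower,
                     upper = ov$upper)
    }))
  }
  post_stratify(fit, strata, scale, hr_cap = cap)
}
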