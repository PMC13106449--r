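# Post-stratified prevalence from latent-model draws, subgroup breakdowns,
# and the Rogan-Gladen closed-form correction.

# Per-draw latent case counts aggregated to arbitrary cell subsets.
# Returns a draws x n_cells matrix given a list of group-index vectors.
cell_count_draws <- function(fit, cell_groups) {
  counts <- do.call(rbind, purrr::map(fit$chains, "counts"))
  vapply(cell_groups,
         function(g) rowSums(counts[, g, drop = FALSE]),
         numeric(nrow(counts)))
}

# Draws x strata matrix of stratum prevalence (denominator: all sampled
# children in the stratum, screen-negatives counting zero cases).
stratum_prevalence_draws <- function(fit) {
  strata <- fit$strata
  groups <- fit$groups
  cg <- purrr::map(strata$stratum, \(s) groups$group[groups$stratum == s])
  n_s <- purrr::map_dbl(strata$stratum,
                        \(s) sum(groups$n_sampled[groups$stratum == s]))
  if (any(n_s == 0)) {
    abort("A stratum has zero sampled children.",
          class = "twophaseprev_config_error")
  }
  d <- sweep(cell_count_draws(fit, cg), 2, n_s, "/")
  colnames(d) <- strata$stratum
  d
}

summarize_draws <- function(d, scale) {
  mult <- if (scale == "per_1000") 1000 else 1
  tibble::tibble(median = mult * median(d),
                 lower = mult * quantile(d, 0.025, names = FALSE),
                 upper = mult * quantile(d, 0.975, names = FALSE))
}

#' Post-stratified prevalence
#'
#' Combines per-draw stratum prevalences with known stratum population sizes:
#' for every draw, `overall = sum(N_s * prev_s) / sum(N_s)`; the posterior is
#' then summarized by its median and equal-tailed 95% credible interval.
#'
#' @param fit A [fit_latent_model()] result.
#' @param strata A [stratum_specs()] table with population sizes; defaults to
#'   the one the fit carries.
#' @param scale `"per_1000"` (default) or `"per_1"`.
#' @param hr_cap Optional upper bound applied, per draw, to the HR stratum
#'   prevalence before post-stratification (see [cap_hr()]).
#' @param screening_sensitivity Optional assumed sensitivity of the
#'   screening stage itself, in (0, 1]. The primary analysis counts
#'   screen-negative children as zero cases; false-negative rates below the
#'   screen cannot be estimated from a two-phase design that never
#'   diagnoses screen-negatives. Supplying a value divides each stratum's
#'   per-draw case total by it (capped at 1), an explicit what-if correction
#'   for screening false negatives.
#' @return A `prevalence_result` tibble: one `"overall"` row plus one row per
#'   stratum, columns `level`, `stratum`, `median`, `lower`, `upper`,
#'   `scale`. The per-draw overall prevalence vector is attached as attribute
#'   `"overall_draws"`.
#' @export
post_stratify <- function(fit, strata = fit$strata,
                          scale = c("per_1000", "per_1"), hr_cap = NULL,
                          screening_sensitivity = NULL) {
  scale <- match.arg(scale)
  if (is.null(strata)) {
    abort("Stratum population sizes are required.",
          class = "twophaseprev_config_error")
  }
  if (!all(fit$groups$stratum %in% strata$stratum)) {
    abort("Missing population size for a sampled stratum.",
          class = "twophaseprev_config_error")
  }
  d <- stratum_prevalence_draws(fit)
  strata <- strata[match(colnames(d), strata$stratum), ]
  if (!is.null(screening_sensitivity)) {
    check_prob(screening_sensitivity, "screening_sensitivity")
    if (screening_sensitivity == 0) {
      abort("`screening_sensitivity` must be in (0, 1].")
    }
    d <- pmin(d / screening_sensitivity, 1)
  }
  if (!is.null(hr_cap)) {
    check_prob(hr_cap, "hr_cap")
    if (hr_cap == 0) abort("`hr_cap` must be in (0, 1].")
    if (!"HR" %in% colnames(d)) {
      abort("No HR stratum present; cannot apply an HR cap.",
            class = "twophaseprev_config_error")
    }
    d[, "HR"] <- pmin(d[, "HR"], hr_cap)
  }
  w <- strata$n_population / sum(strata$n_population)
  overall <- as.numeric(d %*% w)
  out <- dplyr::bind_rows(
    dplyr::mutate(summarize_draws(overall, scale),
                  level = "overall", stratum = NA_character_),
    purrr::map_dfr(colnames(d), \(s)
      dplyr::mutate(summarize_draws(d[, s], scale),
                    level = "stratum", stratum = s))) |>
    dplyr::mutate(scale = scale) |>
    dplyr::relocate("level", "stratum")
  attr(out, "overall_draws") <- overall
  class(out) <- c("prevalence_result", class(out))
  out
}

#' Per-child posterior case probabilities
#'
#' For participants: the posterior mean of the latent status given their
#' observed diagnosis (the average of the sampled `z_i`). For
#' non-participants: the posterior mean of `plogis(beta0 + beta1 * scq_i)`
#' over the coefficient draws — the model-based imputation through which
#' non-participants enter the prevalence estimate.
#'
#' @param fit A [fit_latent_model()] result.
#' @return A tibble `id`, `participant`, `probability`, one row per
#'   screen-positive child, in fit order.
#' @export
posterior_case_probabilities <- function(fit) {
  rec <- fit$records_sp
  d <- param_draws(fit)
  prob <- numeric(nrow(rec))
  prob[rec$participant] <- fit$pz_participants$probability
  nonp <- which(!rec$participant)
  if (length(nonp)) {
    b0 <- d[, "beta0"]
    b1 <- if (fit$intercept_only) 0 else d[, "beta1"]
    prob[nonp] <- purrr::map_dbl(rec$x[nonp],
                                 \(xi) mean(plogis(b0 + b1 * xi)))
  }
  tibble::tibble(id = rec$id, participant = rec$participant,
                 probability = prob)
}

#' Prevalence broken down by sex or grade
#'
#' Post-stratification restricted to each subgroup. Subgroup population
#' sizes are the stratum population sizes shared out in proportion to the
#' subgroup's sampled share within the stratum (the sample's sex/grade
#' composition is taken to represent the stratum's). Subgroups with no
#' sampled children are absent from the output, not reported as zero.
#'
#' @param fit A [fit_latent_model()] result.
#' @param by `"sex"` or `"grade"`.
#' @param strata,scale As in [post_stratify()].
#' @return A `prevalence_result`-style tibble, one row per subgroup. For
#'   `by = "sex"` the adjusted male:female rate ratio (ratio of posterior
#'   median rates, plus the equal-tailed 95% CrI of the per-draw ratio) is
#'   attached as attribute `"adjusted_ratio"`.
#' @export
sex_grade_breakdown <- function(fit, by = c("sex", "grade"),
                                strata = fit$strata,
                                scale = c("per_1000", "per_1")) {
  by <- match.arg(by)
  scale <- match.arg(scale)
  groups <- fit$groups
  strata <- strata[match(unique(groups$stratum), strata$stratum), ]
  n_s <- setNames(
    purrr::map_dbl(strata$stratum,
                   \(s) sum(groups$n_sampled[groups$stratum == s])),
    strata$stratum)
  levels <- sort(unique(groups[[by]]))
  res <- purrr::map(levels, function(g) {
    sub <- groups[groups[[by]] == g, ]
    # per stratum within subgroup: prevalence and population share
    cells <- split(sub$group, sub$stratum)
    n_sg <- purrr::map_dbl(cells, \(gr) sum(sub$n_sampled[sub$group %in% gr]))
    cnt <- cell_count_draws(fit, cells)
    prev_sg <- sweep(cnt, 2, n_sg, "/")
    N_sg <- strata$n_population[match(names(cells), strata$stratum)] *
      n_sg / n_s[names(cells)]
    draws <- as.numeric(prev_sg %*% (N_sg / sum(N_sg)))
    dplyr::mutate(summarize_draws(draws, scale), level = by,
                  group = as.character(g), n_sampled = sum(n_sg)) |>
      dplyr::relocate("level", "group")
  })
  out <- dplyr::bind_rows(res) |> dplyr::mutate(scale = scale)
  if (by == "sex" && all(c("M", "F") %in% out$group)) {
    # per-draw ratio needs the subgroup draw vectors; recompute cheaply
    get_draws <- function(g) {
      sub <- groups[groups[[by]] == g, ]
      cells <- split(sub$group, sub$stratum)
      n_sg <- purrr::map_dbl(cells,
                             \(gr) sum(sub$n_sampled[sub$group %in% gr]))
      N_sg <- strata$n_population[match(names(cells), strata$stratum)] *
        n_sg / n_s[names(cells)]
      as.numeric(sweep(cell_count_draws(fit, cells), 2, n_sg, "/") %*%
                   (N_sg / sum(N_sg)))
    }
    dm <- get_draws("M"); df <- get_draws("F")
    ratio_draws <- dm[df > 0] / df[df > 0]
    attr(out, "adjusted_ratio") <- list(
      ratio = out$median[out$group == "M"] / out$median[out$group == "F"],
      lower = quantile(ratio_draws, 0.025, names = FALSE),
      upper = quantile(ratio_draws, 0.975, names = FALSE))
  }
  out
}

#' Rogan-Gladen misclassification correction
#'
#' Back-corrects an apparent (test-positive) prevalence for known test
#' sensitivity and specificity: `(p + sp - 1) / (se + sp - 1)`, clamped to
#' `[0, 1]` with the clamping flagged. This closed form is the large-sample
#' limit of the intercept-only latent model and serves as its oracle.
#'
#' @param apparent_prev Apparent prevalence(s) in `[0, 1]`; vectorized.
#' @param se,sp Sensitivity and specificity; must satisfy `se + sp > 1`.
#' @return A tibble `apparent`, `estimate` (clamped), `raw`, `clamped`.
#' @examples
#' rogan_gladen(0.4, 0.85, 0.75) # estimate 0.25
#' @export
rogan_gladen <- function(apparent_prev, se, sp) {
  check_prob(apparent_prev, "apparent_prev")
  check_prob(se, "se"); check_prob(sp, "sp")
  if (se + sp <= 1) {
    abort("se + sp must exceed 1.",
          class = "twophaseprev_identifiability_error")
  }
  raw <- (apparent_prev + sp - 1) / (se + sp - 1)
  tibble::tibble(apparent = apparent_prev,
                 estimate = pmin(1, pmax(0, raw)),
                 raw = raw,
                 clamped = raw < 0 | raw > 1)
}
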