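# Diagnostic-phase participation among screen-positives, modelled by
# maximum-likelihood logistic regression. The fit itself is stats::glm
# (IRLS); this module owns the restriction to screen-positives, the
# degenerate-data guards, and the tidy reporting surface.

#' Fit the participation model
#'
#' Logistic regression of `participated` on the requested covariates among
#' screen-positive children. Identifies whether non-participation is
#' associated with symptom severity (the SCQ total) — the justification for
#' carrying the SCQ score into the latent prevalence model.
#'
#' @param records A validated cohort tibble.
#' @param covariates Character vector naming covariates among
#'   `"scq_score"`, `"sex"`, `"grade"` (grade enters as an ordinal 1-3
#'   numeric). Default: all three, jointly.
#' @return A `participation_fit` object: list with `model` (the glm),
#'   `converged`, `separation` flag, `n`, and `covariates`. Use [tidy()] for
#'   the coefficient table and [glance()] for fit-level summaries.
#' @export
fit_participation <- function(records,
                              covariates = c("scq_score", "sex", "grade")) {
  validate_cohort(records)
  if (length(covariates) < 1) abort("At least one covariate is required.")
  bad <- setdiff(covariates, c("scq_score", "sex", "grade"))
  if (length(bad)) {
    abort(sprintf("Unknown covariate(s): %s.", paste(bad, collapse = ", ")),
          class = "twophaseprev_input_error")
  }
  dat <- records |>
    dplyr::filter(.data$screen_positive) |>
    dplyr::mutate(sex = as.integer(.data$sex == "M"),
                  grade = as.numeric(.data$grade),
                  participated = as.integer(.data$participated))
  if (nrow(dat) == 0) abort("No screen-positive children in `records`.")
  if (length(unique(dat$participated)) < 2) {
    abort("Participation outcome is constant: degenerate fit.",
          class = "twophaseprev_degenerate_error")
  }
  for (cv in covariates) {
    if (var(dat[[cv]]) == 0) {
      abort(sprintf("Covariate `%s` has zero variance among screen-positives.",
                    cv),
            class = "twophaseprev_degenerate_error")
    }
  }
  form <- stats::reformulate(covariates, response = "participated")
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dat,
        control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) invokeRestart("muffleWarning"))
  # Fitted probabilities pinned at 0/1 signal (quasi-)complete separation:
  # the MLE is on the boundary and Wald inference is meaningless.
  sep <- any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  structure(list(model = fit,
                 converged = fit$converged && !sep,
                 separation = sep,
                 n = nrow(dat),
                 covariates = covariates),
            class = "participation_fit")
}

#' @export
print.participation_fit <- function(x, ...) {
  cat(sprintf("Participation model (logistic), n = %d screen-positives\n",
              x$n))
  if (!x$converged) {
    cat(if (x$separation) "NOT CONVERGED: complete/quasi-complete separation\n"
        else "NOT CONVERGED\n")
  }
  print(tidy(x), ...)
  invisible(x)
}

#' @rdname fit_participation
#' @param x A `participation_fit`.
#' @param ... Unused.
#' @method tidy participation_fit
#' @export
tidy.participation_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(s),
                 estimate = s[, "Estimate"],
                 std_error = s[, "Std. Error"],
                 statistic = s[, "z value"],
                 p_value = s[, "Pr(>|z|)"])
}

#' @rdname fit_participation
#' @method glance participation_fit
#' @export
glance.participation_fit <- function(x, ...) {
  tibble::tibble(n = x$n, converged = x$converged,
                 separation = x$separation,
                 deviance = x$model$deviance,
                 null_deviance = x$model$null.deviance,
                 aic = x$model$aic)
}

#' Per-child participation probabilities
#'
#' Evaluates the logistic participation model for each screen-positive child.
#' Either a converged [fit_participation()] object or explicit coefficients
#' (named as the model terms, e.g. `c("(Intercept)" = -3.2, scq_score =
#' 0.15)`) may be supplied; the latter is useful for checking against known
#' generator coefficients.
#'
#' @param fit A converged `participation_fit`, or `NULL` when `coefficients`
#'   is given.
#' @param records A validated cohort tibble.
#' @param coefficients Optional named numeric vector overriding the fit.
#' @return A tibble `id`, `probability` for the screen-positive children, in
#'   record order; probabilities strictly inside (0, 1).
#' @export
participation_weights <- function(fit, records, coefficients = NULL) {
  validate_cohort(records)
  dat <- records |>
    dplyr::filter(.data$screen_positive) |>
    dplyr::mutate(sex = as.integer(.data$sex == "M"),
                  grade = as.numeric(.data$grade))
  if (is.null(coefficients)) {
    if (!inherits(fit, "participation_fit")) {
      abort("`fit` must be a participation_fit (or supply `coefficients`).")
    }
    if (!fit$converged) {
      abort("Refusing to compute weights from a non-converged fit.",
            class = "twophaseprev_degenerate_error")
    }
    p <- predict(fit$model, newdata = dat, type = "response")
  } else {
    eta <- rep(coefficients[["(Intercept)"]] %||% 0, nrow(dat))
    for (term in setdiff(names(coefficients), "(Intercept)")) {
      if (!term %in% names(dat)) {
        abort(sprintf("Coefficient `%s` matches no covariate.", term))
      }
      eta <- eta + coefficients[[term]] * dat[[term]]
    }
    p <- plogis(eta)
  }
  tibble::tibble(id = dat$id, probability = as.numeric(p))
}

#' Inverse-probability-weighted crude prevalence (cross-check utility)
#'
#' A non-Bayesian, participation-adjusted crude estimate: among participants,
#' each positive diagnosis is weighted by the inverse of the child's
#' estimated participation probability, totalled per stratum over all
#' screened children, and post-stratified by known population sizes.
#' Offered only as a rough cross-check on the latent-model estimate; the
#' primary analysis adjusts for participation inside the Bayesian model, not
#' by weighting. How exactly a pre-Bayesian "adjusted for participation
#' bias" pooled figure should be computed is an interpretation, and this is
#' the package's.
#'
#' @param records A validated cohort tibble.
#' @param fit A converged `participation_fit` (SCQ-only models are typical).
#' @param strata A [stratum_specs()] table; defaults to the cohort attribute.
#' @return A tibble with per-stratum and overall crude prevalence per 1,000.
#' @export
ipw_prevalence <- function(records, fit,
                           strata = attr(records, "strata")) {
  validate_cohort(records)
  if (is.null(strata)) abort("`strata` required (population sizes).")
  w <- participation_weights(fit, records)
  dat <- records |>
    dplyr::left_join(w, by = "id") |>
    dplyr::mutate(case_wt = ifelse(
      !is.na(.data$diagnosis) & .data$diagnosis == "positive",
      1 / .data$probability, 0))
  per <- dat |>
    dplyr::group_by(stratum = .data$stratum) |>
    dplyr::summarise(n_sampled = dplyr::n(),
                     weighted_cases = sum(.data$case_wt, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(prevalence = pmin(1, .data$weighted_cases /
                                      .data$n_sampled)) |>
    dplyr::left_join(strata[c("stratum", "n_population")], by = "stratum")
  overall <- sum(per$n_population * per$prevalence) / sum(per$n_population)
  dplyr::bind_rows(
    per |> dplyr::transmute(level = "stratum", stratum = .data$stratum,
                            prevalence_per_1000 =
                              per_thousand(.data$prevalence)),
    tibble::tibble(level = "overall", stratum = NA_character_,
                   prevalence_per_1000 = per_thousand(overall)))
}
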