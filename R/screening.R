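# SCQ scoring, cutoff classification, and two-phase flow bookkeeping.

#' Screening configuration
#'
#' @param cutoff Screen-positive threshold: a total score at or above it is
#'   positive. The default 11 prioritizes sensitivity for two-phase
#'   epidemiological use; the clinically common 15 is available by setting
#'   `cutoff = 15`.
#' @param max_score Maximum attainable total (39 scored items on the Lifetime
#'   form).
#' @return A `screen_config` list.
#' @export
screen_config <- function(cutoff = 11L, max_score = 39L) {
  cutoff <- check_count(cutoff, "cutoff")
  max_score <- check_count(max_score, "max_score", positive = TRUE)
  if (cutoff < 0 || cutoff > max_score) {
    abort("`cutoff` must lie in [0, max_score].",
          class = "twophaseprev_config_error")
  }
  structure(list(cutoff = cutoff, max_score = max_score),
            class = "screen_config")
}

#' Total an SCQ item-response vector
#'
#' Sums the 39 scored binary items of the Lifetime form. When only totals are
#' available (the usual synthetic path) this entry point is bypassed and the
#' total enters [classify_screen()] directly.
#'
#' @param item_responses Binary (0/1 or logical) vector of length 39.
#' @return Integer total in 0-39.
#' @export
score_scq <- function(item_responses) {
  x <- item_responses
  if (is.logical(x)) x <- as.integer(x)
  if (!is.numeric(x) || length(x) != 39) {
    abort("`item_responses` must have exactly 39 entries.",
          class = "twophaseprev_input_error")
  }
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    abort("`item_responses` must be binary (0/1) with no missing values.",
          class = "twophaseprev_input_error")
  }
  as.integer(sum(x))
}

#' Classify a total score against the screening cutoff
#'
#' @param score Integer total(s) in `[0, max_score]`; vectorized.
#' @param config A [screen_config()].
#' @return Logical: `TRUE` iff `score >= cutoff`.
#' @export
classify_screen <- function(score, config = screen_config()) {
  if (!is.numeric(score) || anyNA(score) ||
      any(score < 0 | score > config$max_score) ||
      any(score != trunc(score))) {
    abort(sprintf("`score` must be integer in [0, %d].", config$max_score),
          class = "twophaseprev_input_error")
  }
  score >= config$cutoff
}

#' Summarize the two-phase participant flow
#'
#' Counts, per stratum and overall, the monotone chain screened ->
#' screen-positive (= eligible for diagnosis) -> participated ->
#' diagnosed-positive, with the diagnostic-phase response rate
#' `participated / screen_positive`. When `strata` (a [stratum_specs()]
#' table, possibly with an `n_invited` column) is supplied, an invited count
#' and screening-phase response rate are included.
#'
#' @param records A validated cohort tibble.
#' @param strata Optional [stratum_specs()] table; defaults to the cohort's
#'   `strata` attribute when present.
#' @return A `phase_summary` tibble with one row per stratum plus a
#'   `"Total"` row.
#' @export
summarize_flow <- function(records, strata = attr(records, "strata")) {
  validate_cohort(records)
  per <- records |>
    dplyr::group_by(stratum = .data$stratum) |>
    dplyr::summarise(
      screened = dplyr::n(),
      screen_positive = sum(.data$screen_positive),
      eligible = sum(.data$screen_positive),
      participated = sum(.data$participated, na.rm = TRUE),
      diagnosed_positive = sum(.data$diagnosis == "positive", na.rm = TRUE),
      .groups = "drop"
    )
  tot <- per |>
    dplyr::summarise(dplyr::across(-"stratum", sum)) |>
    dplyr::mutate(stratum = "Total", .before = 1)
  out <- dplyr::bind_rows(per, tot) |>
    dplyr::mutate(diagnostic_response_rate = ifelse(
      .data$screen_positive > 0,
      .data$participated / .data$screen_positive, NA_real_))
  if (!is.null(strata) && "n_invited" %in% names(strata)) {
    inv <- c(setNames(strata$n_invited, strata$stratum),
             Total = sum(strata$n_invited))
    out <- out |>
      dplyr::mutate(invited = unname(inv[.data$stratum]),
                    screening_response_rate = .data$screened / .data$invited,
                    .after = "stratum")
  }
  class(out) <- c("phase_summary", class(out))
  out
}
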