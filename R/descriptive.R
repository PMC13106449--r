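# Descriptive / administrative prevalence arithmetic: simple proportions per
# 1,000 with Wald (and optionally exact) intervals, sex ratios, percent change
# and sampling-coverage fractions.

#' Administrative prevalence from case counts
#'
#' Computes prevalence as a simple proportion `cases / total`, scaled per
#' 1,000, with a 95% confidence interval. The primary interval is the normal
#' approximation (Wald) on the proportion; a Clopper-Pearson exact interval is
#' returned alongside it, and is the one to trust when `cases` is 0 or very
#' small (the Wald interval degenerates there and is flagged).
#'
#' @param counts A data frame with columns `period` (label), `cases`
#'   (non-negative integer) and `total` (positive integer); one row per
#'   reporting period. A single period may also be given via `cases` and
#'   `total` directly.
#' @param cases,total Scalar shortcut for a single period (ignored when
#'   `counts` is supplied).
#' @param conf_level Confidence level, default 0.95.
#'
#' @return A tibble with one row per period: `period`, `cases`, `total`,
#'   `prevalence_per_1000`, `ci_lower_per_1000`, `ci_upper_per_1000` (Wald),
#'   `exact_lower_per_1000`, `exact_upper_per_1000` (Clopper-Pearson),
#'   `wald_degenerate` flag and `method`. Display rounding is left to the
#'   caller; values are full precision.
#' @examples
#' admin_prevalence(cases = 194, total = 38748)
#' @export
admin_prevalence <- function(counts = NULL, cases = NULL, total = NULL,
                             conf_level = 0.95) {
  if (is.null(counts)) {
    counts <- tibble::tibble(period = NA_character_, cases = cases,
                             total = total)
  }
  counts <- tibble::as_tibble(counts)
  if (!all(c("cases", "total") %in% names(counts))) {
    abort("`counts` needs columns `cases` and `total`.")
  }
  if (!"period" %in% names(counts)) counts$period <- NA_character_
  purrr::pwalk(counts, function(cases, total, ...) {
    check_count(cases, "cases"); check_count(total, "total", positive = TRUE)
    if (cases > total) abort("`cases` must not exceed `total`.")
  })
  z <- qnorm(1 - (1 - conf_level) / 2)
  counts |>
    dplyr::mutate(
      p = .data$cases / .data$total,
      se = sqrt(.data$p * (1 - .data$p) / .data$total),
      prevalence_per_1000 = per_thousand(.data$p),
      ci_lower_per_1000 = per_thousand(pmax(0, .data$p - z * .data$se)),
      ci_upper_per_1000 = per_thousand(pmin(1, .data$p + z * .data$se)),
      exact_lower_per_1000 = per_thousand(purrr::map2_dbl(
        .data$cases, .data$total,
        ~ stats::binom.test(.x, .y, conf.level = conf_level)$conf.int[1])),
      exact_upper_per_1000 = per_thousand(purrr::map2_dbl(
        .data$cases, .data$total,
        ~ stats::binom.test(.x, .y, conf.level = conf_level)$conf.int[2])),
      wald_degenerate = .data$cases == 0 | .data$cases == .data$total,
      method = "wald"
    ) |>
    dplyr::select(-"p", -"se")
}

#' Male-to-female case ratio
#'
#' @param male_cases,female_cases Non-negative case counts.
#' @return The ratio `male_cases / female_cases` (full precision; round to one
#'   decimal for display). `NA` with a warning when `female_cases` is 0 — the
#'   ratio is undefined, not infinite, for reporting purposes.
#' @examples
#' sex_ratio(35, 11) # 3.18..., prints as 3.2
#' @export
sex_ratio <- function(male_cases, female_cases) {
  check_count(male_cases, "male_cases")
  check_count(female_cases, "female_cases")
  if (female_cases == 0) {
    warn("`female_cases` is 0: sex ratio undefined, returning NA.")
    return(NA_real_)
  }
  male_cases / female_cases
}

#' Percent change between two rates
#'
#' @param old_value Baseline rate; must be positive.
#' @param new_value New rate.
#' @return `100 * (new_value - old_value) / old_value`.
#' @examples
#' percent_change(6.7, 32.2) # 380.6
#' @export
percent_change <- function(old_value, new_value) {
  if (!is.numeric(old_value) || !is.finite(old_value) || old_value <= 0) {
    abort("`old_value` must be a positive number.")
  }
  100 * (new_value - old_value) / old_value
}

#' Sampling coverage fraction
#'
#' Fraction of a target subpopulation covered by the sample, in percent.
#'
#' @param sampled Number sampled; must satisfy `0 <= sampled <= target`.
#' @param target Target subpopulation size; must be positive.
#' @return `100 * sampled / target`.
#' @examples
#' coverage_fraction(8565, 34392) # 24.9
#' @export
coverage_fraction <- function(sampled, target) {
  check_count(sampled, "sampled")
  check_count(target, "target", positive = TRUE)
  if (sampled > target) abort("`sampled` must not exceed `target`.")
  100 * sampled / target
}

#' Read administrative case counts from CSV
#'
#' Expects columns `period,cases,total`. Thousands separators (spaces) and
#' mid-dot decimal marks, as found in transcribed report tables, are
#' tolerated.
#'
#' @param path CSV file path.
#' @return A tibble suitable for [admin_prevalence()].
#' @export
read_admin_counts <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("period", "cases", "total") %in% names(raw))) {
    abort("Admin counts CSV needs columns period, cases, total.")
  }
  clean <- function(x) as.integer(gsub("[  ]", "", x))
  tibble::tibble(period = raw$period, cases = clean(raw$cases),
                 total = clean(raw$total))
}
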