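# Cohort CSV round-trip and structural validation.
#
# Column contract: id,stratum,grade,sex,scq_score,screen_positive,
# participated,diagnosis,true_status. `participated` is empty for
# screen-negatives; `diagnosis` is empty unless the child participated;
# `true_status` is optional (synthetic cohorts only).

cohort_columns <- c("id", "stratum", "grade", "sex", "scq_score",
                    "screen_positive", "participated", "diagnosis",
                    "true_status")

#' Validate a cohort table
#'
#' Checks the structural invariants every downstream stage relies on: known
#' stratum labels, grades 1-3, sex M/F, SCQ totals in 0-39, `participated`
#' defined exactly for screen-positives, and `diagnosis` present exactly for
#' participants. Errors name the first offending row.
#'
#' @param records A cohort tibble (see [simulate_population()]).
#' @return `records`, invisibly, if valid.
#' @export
validate_cohort <- function(records) {
  records <- tibble::as_tibble(records)
  need <- setdiff(setdiff(cohort_columns, "true_status"), names(records))
  if (length(need)) {
    abort(sprintf("Cohort is missing column(s): %s.",
                  paste(need, collapse = ", ")),
          class = "twophaseprev_parse_error")
  }
  fail <- function(cond, what) {
    bad <- which(cond)
    if (length(bad)) {
      abort(sprintf("Invalid cohort: %s (first offending row %d).",
                    what, bad[1]),
            class = "twophaseprev_parse_error")
    }
  }
  fail(!records$stratum %in% stratum_levels, "unknown stratum label")
  fail(!records$grade %in% 1:3, "grade outside 1-3")
  fail(!records$sex %in% c("M", "F"), "sex must be M or F")
  fail(is.na(records$scq_score) | records$scq_score < 0 |
         records$scq_score > 39, "scq_score outside [0, 39]")
  fail(is.na(records$screen_positive), "screen_positive missing")
  fail(!records$screen_positive & !is.na(records$participated),
       "participated defined for a screen-negative child")
  fail(records$screen_positive & is.na(records$participated),
       "participated missing for a screen-positive child")
  diag_ok <- records$diagnosis %in% c("positive", "negative")
  observed <- records$screen_positive & !is.na(records$participated) &
    records$participated
  fail(observed & !diag_ok, "diagnosis missing for a participant")
  fail(!observed & !is.na(records$diagnosis),
       "diagnosis present for a non-participant")
  invisible(records)
}

#' Write a cohort to CSV
#'
#' @param records A validated cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  validate_cohort(records)
  out <- tibble::as_tibble(records)
  if (!"true_status" %in% names(out)) out$true_status <- NA
  out <- out[cohort_columns]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Inverse of [write_cohort()]: `read_cohort(write_cohort(x)) == x` up to the
#' optional `true_status` column. Malformed rows fail validation with the row
#' number named.
#'
#' @param path CSV file path.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  records <- readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      id = "c", stratum = "c", grade = "i", sex = "c", scq_score = "i",
      screen_positive = "l", participated = "l", diagnosis = "c",
      true_status = "l"
    ))
  probs <- readr::problems(records)
  if (nrow(probs)) {
    abort(sprintf("Cohort CSV parse failure at row %d: %s.",
                  probs$row[1], probs$expected[1]),
          class = "twophaseprev_parse_error")
  }
  if (all(is.na(records$true_status))) records$true_status <- NULL
  validate_cohort(records)
  records
}
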