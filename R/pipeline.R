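# End-to-end orchestration: simulate/load -> screen -> participation ->
# latent fit -> post-stratify -> diagnostics -> optional sensitivity
# analyses, with a reproducible on-disk result bundle.

#' Pipeline run configuration
#'
#' Exactly one of `cohort_path` (a cohort CSV) or `sim` (a [sim_config()])
#' supplies the data.
#'
#' @param cohort_path Path to a cohort CSV readable by [read_cohort()].
#' @param sim A [sim_config()] for a synthetic cohort.
#' @param strata A [stratum_specs()] table; required with `cohort_path`,
#'   defaults to the simulation's strata otherwise.
#' @param screen A [screen_config()] (bookkeeping only; screen status is
#'   already materialized in the cohort).
#' @param model A [latent_model_spec()].
#' @param mcmc An [mcmc_spec()].
#' @param grid `NULL` to skip the deterministic sensitivity grid, or a
#'   [grid_spec()].
#' @param caps `NULL` to skip HR-cap scenarios, or a [cap_spec()].
#' @param beta_priors `NULL` to skip the probabilistic sensitivity analysis,
#'   or a list `list(se = c(a, b), sp = c(a, b))`.
#' @param out_dir Output directory for the bundle; created if absent.
#' @param seed Integer seed recorded in, and driving, the whole run.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort_path = NULL, sim = NULL, strata = NULL,
                       screen = screen_config(),
                       model = latent_model_spec(), mcmc = NULL,
                       grid = NULL, caps = cap_spec(), beta_priors = NULL,
                       out_dir = tempfile("twophaseprev-run-"),
                       seed = 1L) {
  if (is.null(cohort_path) == is.null(sim)) {
    abort("Supply exactly one of `cohort_path` or `sim`.",
          class = "twophaseprev_config_error")
  }
  if (!is.null(cohort_path) && is.null(strata)) {
    abort("`strata` (population sizes) is required with `cohort_path`.",
          class = "twophaseprev_config_error")
  }
  seed <- check_count(seed, "seed")
  if (is.null(mcmc)) mcmc <- mcmc_spec(seed = seed)
  structure(list(cohort_path = cohort_path, sim = sim, strata = strata,
                 screen = screen, model = model, mcmc = mcmc, grid = grid,
                 caps = caps, beta_priors = beta_priors, out_dir = out_dir,
                 seed = seed),
            class = "run_config")
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

#' Run the full two-phase prevalence pipeline
#'
#' Executes every stage in order and writes a deterministic result bundle to
#' `config$out_dir`: the cohort (if simulated), the flow summary, the
#' participation fit, the primary prevalence estimates with sex/grade
#' breakdowns, the convergence report, and any requested sensitivity
#' analyses, plus an echo of the configuration and seed and a Markdown
#' summary. Identical configurations produce identical bundles.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage progress messages.
#' @return (Invisibly) a list with all in-memory results: `cohort`, `flow`,
#'   `participation`, `fit`, `prevalence`, `by_sex`, `by_grade`,
#'   `diagnostics`, and optionally `grid`, `caps`, `probabilistic`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config.")
  say <- function(...) if (!quiet) message("[", ..., "]")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }

  cohort <- stage("data", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- config$seed
      cohort <- simulate_population(sim)
      write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
      cohort
    } else {
      cohort <- read_cohort(config$cohort_path)
      attr(cohort, "strata") <- config$strata
      cohort
    }
  })
  strata <- config$strata %||% attr(cohort, "strata")

  flow <- stage("screening", {
    flow <- summarize_flow(cohort, strata)
    readr::write_csv(flow, file.path(config$out_dir, "flow_summary.csv"))
    flow
  })

  part <- stage("participation", {
    part <- fit_participation(cohort)
    write_json_out(list(coefficients = tidy(part), summary = glance(part)),
                   file.path(config$out_dir, "participation.json"))
    part
  })

  fit <- stage("latent_model", {
    mcmc <- config$mcmc
    mcmc$seed <- split_seed(config$seed, 7)
    fit_latent_model(cohort, config$model, mcmc, strata)
  })

  results <- stage("post_stratify", {
    prevalence <- post_stratify(fit, strata)
    by_sex <- sex_grade_breakdown(fit, "sex", strata)
    by_grade <- sex_grade_breakdown(fit, "grade", strata)
    readr::write_csv(prevalence, file.path(config$out_dir,
                                           "prevalence.csv"))
    write_json_out(list(
      overall = as.list(prevalence[prevalence$level == "overall",
                                   c("median", "lower", "upper")]),
      strata = prevalence[prevalence$level == "stratum", ],
      by_sex = by_sex, adjusted_sex_ratio = attr(by_sex, "adjusted_ratio"),
      by_grade = by_grade, scale = "per_1000"),
      file.path(config$out_dir, "prevalence.json"))
    list(prevalence = prevalence, by_sex = by_sex, by_grade = by_grade)
  })

  diagnostics <- stage("diagnostics", {
    rep <- diagnose_fit(fit)
    write_json_out(list(parameters = rep, pass = attr(rep, "pass"),
                        n_chains = attr(rep, "n_chains"),
                        draws_per_chain = attr(rep, "draws_per_chain")),
                   file.path(config$out_dir, "diagnostics.json"))
    rep
  })

  out <- list(cohort = cohort, flow = flow, participation = part, fit = fit,
              prevalence = results$prevalence, by_sex = results$by_sex,
              by_grade = results$by_grade, diagnostics = diagnostics)

  if (!is.null(config$grid)) {
    out$grid <- stage("sensitivity_grid", {
      g <- deterministic_grid(cohort, config$model, config$grid,
                              config$mcmc, strata)
      readr::write_csv(g, file.path(config$out_dir,
                                    "sensitivity_grid.csv"))
      g
    })
  }
  if (!is.null(config$caps)) {
    out$caps <- stage("hr_caps", {
      cp <- cap_hr(fit, config$caps, strata)
      readr::write_csv(cp, file.path(config$out_dir, "hr_caps.csv"))
      cp
    })
  }
  if (!is.null(config$beta_priors)) {
    out$probabilistic <- stage("probabilistic_sensitivity", {
      mcmc <- config$mcmc
      mcmc$seed <- split_seed(config$seed, 8)
      ps <- probabilistic_sensitivity(cohort, config$model,
                                      config$beta_priors$se,
                                      config$beta_priors$sp, mcmc, strata)
      readr::write_csv(ps$misclass,
                       file.path(config$out_dir,
                                 "probabilistic_misclass.csv"))
      readr::write_csv(ps$prevalence,
                       file.path(config$out_dir,
                                 "probabilistic_prevalence.csv"))
      ps[c("prevalence", "misclass")]
    })
  }

  stage("report", {
    write_json_out(list(seed = config$seed,
                        mcmc = unclass(config$mcmc),
                        screen_cutoff = config$screen$cutoff,
                        misclass = unclass(config$model$misclass)),
                   file.path(config$out_dir, "run_config.json"))
    writeLines(render_report(out), file.path(config$out_dir, "report.md"))
  })
  say(sprintf("bundle written to %s", config$out_dir))
  invisible(out)
}

render_report <- function(res) {
  ov <- res$prevalence[res$prevalence$level == "overall", ]
  fmt_row <- function(r) sprintf("%.1f (%.1f; %.1f)", r$median, r$lower,
                                 r$upper)
  lines <- c(
    "# Two-phase prevalence run",
    "",
    "## Participant flow",
    knit_table(res$flow),
    "",
    "## Overall prevalence (per 1,000)",
    sprintf("* Post-stratified: %s", fmt_row(ov)),
    sprintf("* By sex: %s",
            paste(sprintf("%s %s", res$by_sex$group,
                          purrr::map_chr(seq_len(nrow(res$by_sex)),
                                         \(i) fmt_row(res$by_sex[i, ]))),
                  collapse = "; ")),
    "",
    "## Convergence",
    knit_table(res$diagnostics))
  if (!is.null(res$caps)) {
    lines <- c(lines, "", "## HR cap scenarios", knit_table(res$caps))
  }
  lines
}

# Minimal Markdown table renderer (no knitr dependency on the run path).
knit_table <- function(df) {
  df <- tibble::as_tibble(df)
  df[] <- lapply(df, \(x) if (is.numeric(x)) round(x, 3) else x)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- purrr::map_chr(seq_len(nrow(df)), \(i)
    paste0("| ", paste(format(unlist(df[i, ]), trim = TRUE),
                       collapse = " | "), " |"))
  c(header, sep, rows)
}
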