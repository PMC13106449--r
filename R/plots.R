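# ggplot2 visualisations. Never on the critical computation path.

#' Trace plot of latent-model parameter draws
#'
#' @param object A `latent_fit`.
#' @param ... Unused.
#' @return A ggplot: one facet per parameter, one colour per chain.
#' @method autoplot latent_fit
#' @export
autoplot.latent_fit <- function(object, ...) {
  d <- purrr::imap_dfr(object$chains, \(ch, i)
    tibble::as_tibble(ch$pars) |>
      dplyr::mutate(chain = factor(i),
                    iteration = dplyr::row_number()) |>
      tidyr::pivot_longer(-c("chain", "iteration"),
                          names_to = "parameter"))
  ggplot2::ggplot(d, ggplot2::aes(.data$iteration, .data$value,
                                  colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Kept iteration", y = "Draw", colour = "Chain")
}

#' Prevalence estimates with credible intervals
#'
#' @param object A `prevalence_result` from [post_stratify()].
#' @param ... Unused.
#' @return A ggplot of medians with 95% CrI error bars.
#' @method autoplot prevalence_result
#' @export
autoplot.prevalence_result <- function(object, ...) {
  d <- dplyr::mutate(object,
                     label = ifelse(.data$level == "overall", "Overall",
                                    .data$stratum))
  ggplot2::ggplot(d, ggplot2::aes(.data$label, .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::labs(x = NULL,
                  y = sprintf("Prevalence (%s)",
                              gsub("_", " ", d$scale[1])))
}

#' Heat map of the deterministic Se x Sp sensitivity grid
#'
#' @param grid_result The tibble returned by [deterministic_grid()].
#' @param scale Label for the fill legend; the grid is stored per 1,000.
#' @return A ggplot tile map, each cell labelled with its median (and CrI).
#' @export
plot_sensitivity_grid <- function(grid_result, scale = "per 1,000") {
  ggplot2::ggplot(grid_result,
                  ggplot2::aes(factor(.data$sp), factor(.data$se),
                               fill = .data$median)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf(
      "%.1f\n(%.1f; %.1f)", .data$median, .data$lower, .data$upper)),
      size = 2.8) +
    ggplot2::labs(x = "Specificity", y = "Sensitivity",
                  fill = sprintf("Median (%s)", scale))
}

#' High-risk-stratum cap scenarios
#'
#' @param cap_result The tibble returned by [cap_hr()] with a [cap_spec()].
#' @return A ggplot of the overall estimate across cap scenarios.
#' @export
plot_hr_caps <- function(cap_result) {
  ggplot2::ggplot(cap_result,
                  ggplot2::aes(factor(100 * .data$cap), .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::labs(x = "HR stratum cap (%)",
                  y = "Overall prevalence per 1,000")
}
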