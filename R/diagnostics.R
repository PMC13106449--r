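# Convergence diagnostics, implemented at formula level and documented.
#
# R-hat: rank-normalized split potential scale reduction factor. Each chain
# is split in half; all draws are pooled, converted to average ranks r, then
# to normal scores z = qnorm((r - 3/8) / (S + 1/4)); the classic
# sqrt(((n-1)/n W + B/n) / W) statistic is computed on the scores, with W the
# mean within-(split-)chain variance and B = n var(chain means).
#
# ESS: combined-chain autocorrelation ESS with Geyer initial-monotone
# truncation. With per-chain lag-t autocovariances acov_t (FFT, biased /n),
# rho_t = 1 - (W - mean_chain(acov_t)) / var_plus, paired sums
# P_k = rho_{2k} + rho_{2k+1} are truncated before the first negative pair
# and forced non-increasing; ESS = m n / (-1 + 2 sum P'_k).

# Canonicalize input: matrix (iterations x chains, one parameter), list of
# equal-length numeric vectors (one parameter), or list of equal-dim
# matrices with common column names (one column per parameter).
as_chain_list <- function(chains) {
  if (is.matrix(chains)) {
    chains <- purrr::map(seq_len(ncol(chains)), \(j) chains[, j])
  }
  if (!is.list(chains) || length(chains) < 2) {
    abort("`chains` must hold at least 2 chains.",
          class = "twophaseprev_input_error")
  }
  if (is.matrix(chains[[1]])) {
    pars <- colnames(chains[[1]]) %||%
      paste0("par", seq_len(ncol(chains[[1]])))
    out <- purrr::map(seq_along(pars),
                      \(j) purrr::map(chains, \(m) as.numeric(m[, j])))
    names(out) <- pars
  } else {
    out <- list(par = purrr::map(chains, as.numeric))
  }
  n <- purrr::map_int(out[[1]], length)
  if (length(unique(n)) != 1 || n[1] < 4) {
    abort("Chains must have equal length >= 4.",
          class = "twophaseprev_input_error")
  }
  out
}

split_halves <- function(draws) {
  n <- length(draws[[1]])
  half <- n %/% 2
  unlist(purrr::map(draws, \(x) list(x[seq_len(half)],
                                     x[half + seq_len(half)])),
         recursive = FALSE)
}

classic_rhat <- function(m) {
  n <- nrow(m)
  W <- mean(apply(m, 2, var))
  B <- n * var(colMeans(m))
  if (W == 0) return(NaN)
  sqrt(((n - 1) / n * W + B / n) / W)
}

rhat_one <- function(draws) {
  halves <- split_halves(draws)
  flat <- unlist(halves)
  if (var(flat) == 0) return(NaN)
  S <- length(flat)
  z <- qnorm((rank(flat, ties.method = "average") - 3 / 8) / (S + 1 / 4))
  classic_rhat(matrix(z, ncol = length(halves)))
}

acov_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m <- 2^ceiling(log2(2 * n))
  f <- fft(c(xc, rep(0, m - n)))
  Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (m * n)
}

ess_one <- function(draws) {
  halves <- split_halves(draws)
  m <- length(halves)
  n <- length(halves[[1]])
  flat <- unlist(halves)
  if (var(flat) == 0) return(NaN)
  acov <- purrr::map(halves, acov_fft)
  mean_acov <- Reduce(`+`, acov) / m
  W <- mean(purrr::map_dbl(halves, var))
  B <- n * var(purrr::map_dbl(halves, mean))
  var_plus <- (n - 1) / n * W + B / n
  rho <- 1 - (W - mean_acov) / var_plus
  max_pairs <- (n - 2) %/% 2
  tau <- NA_real_
  psum_prev <- Inf
  total <- 0
  for (k in 0:max_pairs) {
    p <- rho[2 * k + 1] + rho[2 * k + 2]
    if (p <= 0) break
    p <- min(p, psum_prev)       # initial monotone sequence
    total <- total + p
    psum_prev <- p
  }
  tau <- max(-1 + 2 * total, 1 / (m * n))
  min(m * n / tau, m * n * log10(m * n))
}

#' Gelman-Rubin split R-hat
#'
#' Rank-normalized split-chain potential scale reduction factor (the exact
#' formula is stated in the source header of this module). Values near 1
#' indicate the chains are mixing over the same distribution; the package
#' warns above 1.01 and fails a report above 1.05.
#'
#' @param chains Draws as a matrix (iterations x chains, one parameter), a
#'   list of equal-length numeric vectors, or a list of per-chain matrices
#'   with one named column per parameter.
#' @return Named numeric vector of R-hat per parameter. Zero-variance
#'   (constant) parameters yield `NaN`, flagged — not an error.
#' @export
gelman_rubin <- function(chains) {
  cl <- as_chain_list(chains)
  out <- purrr::map_dbl(cl, rhat_one)
  if (anyNA(out)) {
    warn(sprintf("R-hat undefined (zero variance) for: %s.",
                 paste(names(out)[is.na(out)], collapse = ", ")))
  }
  out
}

#' Effective sample size
#'
#' Combined-chain autocorrelation ESS with Geyer initial-monotone-sequence
#' truncation (formula in the source header of this module). Bounded above
#' by the total draw count times `log10(total)` as a numerical guard;
#' approximately the total draw count for independent draws.
#'
#' @inheritParams gelman_rubin
#' @return Named numeric vector of ESS per parameter; `NaN` (with a warning)
#'   for constant parameters.
#' @export
effective_sample_size <- function(chains) {
  cl <- as_chain_list(chains)
  out <- purrr::map_dbl(cl, ess_one)
  if (anyNA(out)) {
    warn(sprintf("ESS undefined (zero variance) for: %s.",
                 paste(names(out)[is.na(out)], collapse = ", ")))
  }
  out
}

#' Convergence report for a latent-model fit
#'
#' Computes R-hat and ESS for every sampled model parameter and flags them
#' against thresholds: warn at R-hat > `rhat_warn` or ESS < `ess_warn`; the
#' report fails at R-hat > `rhat_fail`.
#'
#' @param fit A [fit_latent_model()] result.
#' @param rhat_warn,rhat_fail,ess_warn Thresholds (defaults 1.01, 1.05, 400).
#' @return A `diagnostic_report` tibble: `parameter`, `rhat`, `ess`,
#'   `rhat_ok`, `ess_ok`, with attributes `pass` (no parameter beyond
#'   `rhat_fail`), `n_chains`, `draws_per_chain`.
#' @export
diagnose_fit <- function(fit, rhat_warn = 1.01, rhat_fail = 1.05,
                         ess_warn = 400) {
  mats <- purrr::map(fit$chains, "pars")
  rhat <- gelman_rubin(mats)
  ess <- effective_sample_size(mats)
  out <- tibble::tibble(parameter = names(rhat), rhat = unname(rhat),
                        ess = unname(ess),
                        rhat_ok = !is.na(rhat) & rhat <= rhat_warn,
                        ess_ok = !is.na(ess) & ess >= ess_warn)
  attr(out, "pass") <- all(is.na(rhat) | rhat <= rhat_fail)
  attr(out, "n_chains") <- length(mats)
  attr(out, "draws_per_chain") <- nrow(mats[[1]])
  class(out) <- c("diagnostic_report", class(out))
  out
}
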