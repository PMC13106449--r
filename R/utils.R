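# Internal helpers: argument checking and the seed-splitting scheme.

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

check_prob <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) >= 1 && all(is.finite(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) {
    abort(sprintf("`%s` must be a probability in %s.", name,
                  if (open) "(0, 1)" else "[0, 1]"),
          class = "twophaseprev_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, positive = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && x == trunc(x) &&
    (if (positive) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be a %s integer.", name,
                  if (positive) "positive" else "non-negative"),
          class = "twophaseprev_config_error")
  }
  invisible(as.integer(x))
}

# All randomness in the package flows from one integer seed. Sub-streams
# (simulation, each MCMC chain, each sensitivity-grid cell) get seeds derived
# by fixed additive offsets, reduced modulo 2^31 - 1 so they remain valid R
# integer seeds. The scheme is deterministic and documented in the vignette:
#   simulation        -> seed
#   chain c (1-based) -> split_seed(seed, c)
#   grid cell k       -> split_seed(seed, 1000 + k), chains offset within
split_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 747796405 * as.numeric(offset)) %%
               2147483647)
}

per_thousand <- function(x) 1000 * x

round1 <- function(x) round(x, 1)

stratum_levels <- c("LR", "ER", "HR")
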