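# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Deterministic child seed: keeps derived seeds inside 32-bit integer range.
child_seed <- function(seed, k) {
  (as.integer(seed) + 104729L * as.integer(k)) %% .Machine$integer.max
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

# Geometric mean, NA-free input assumed.
geomean <- function(x) exp(mean(log(x)))

# Column-wise sample quantile (type 7) helper for bootstrap CIs.
pct_ci <- function(draws, alpha) {
  stats::quantile(draws, probs = c(alpha / 2, 1 - alpha / 2),
                  names = FALSE, type = 7)
}
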