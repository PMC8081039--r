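# Bootstrap estimation statistics in the estimation-graphics (Gardner-Altman)
# style: effect sizes with bootstrap CIs rather than p-values.

new_effect_size <- function(estimate, ci, n_control, n_test, B, alpha,
                            method, statistic, boot_dist, degenerate = FALSE) {
  structure(
    list(estimate = estimate, ci_low = ci[1], ci_high = ci[2],
         n_control = n_control, n_test = n_test, B = B, alpha = alpha,
         method = method, statistic = statistic, boot_dist = boot_dist,
         degenerate = degenerate),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> %s = %.4g, CI%d%% [%.4g, %.4g] (%s, B = %d)\n",
              x$statistic, x$estimate, round(100 * (1 - x$alpha)),
              x$ci_low, x$ci_high, x$method, x$B))
  invisible(x)
}

#' @method tidy effect_size
#' @export
tidy.effect_size <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, estimate = x$estimate,
                 ci_low = x$ci_low, ci_high = x$ci_high)
}

#' @method glance effect_size
#' @export
glance.effect_size <- function(x, ...) {
  tibble::tibble(n_control = x$n_control, n_test = x$n_test, B = x$B,
                 alpha = x$alpha, method = x$method,
                 degenerate = x$degenerate)
}

# two-group bootstrap of a statistic f(control, test); groups resampled
# independently. Returns the B bootstrap replicates.
boot_two_group <- function(control, test, f, B) {
  nc <- length(control)
  nt <- length(test)
  cm <- matrix(control[sample.int(nc, nc * B, replace = TRUE)], nrow = B)
  tm <- matrix(test[sample.int(nt, nt * B, replace = TRUE)], nrow = B)
  f(cm, tm)
}

# BCa interval from bootstrap replicates + jackknife values of the statistic
bca_ci <- function(boot_dist, estimate, jack, alpha) {
  z0 <- qnorm(mean(boot_dist < estimate) +
                0.5 * mean(boot_dist == estimate))
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  if (!is.finite(z0) || den == 0) return(NULL)  # acceleration undefined
  a <- num / den
  zlo <- qnorm(alpha / 2)
  zhi <- qnorm(1 - alpha / 2)
  p_lo <- pnorm(z0 + (z0 + zlo) / (1 - a * (z0 + zlo)))
  p_hi <- pnorm(z0 + (z0 + zhi) / (1 - a * (z0 + zhi)))
  stats::quantile(boot_dist, probs = c(p_lo, p_hi), names = FALSE, type = 7)
}

two_group_effect <- function(control, test, f, statistic, B, alpha,
                             method, seed) {
  control <- control[is.finite(control)]
  test <- test[is.finite(test)]
  if (length(control) < 3 || length(test) < 3) {
    abort("Both groups need at least 3 values.")
  }
  if (B < 1000) abort("B must be >= 1000 for stable intervals.")
  est <- f(matrix(control, nrow = 1), matrix(test, nrow = 1))

  boot_dist <- with_seed(seed, boot_two_group(control, test, f, B))

  if (all(boot_dist == boot_dist[1])) {
    return(new_effect_size(est, c(est, est), length(control), length(test),
                           B, alpha, "degenerate", statistic, boot_dist,
                           degenerate = TRUE))
  }

  # jackknife over every observation (within its own group)
  jack <- c(
    vapply(seq_along(control), function(i) {
      f(matrix(control[-i], nrow = 1), matrix(test, nrow = 1))
    }, numeric(1)),
    vapply(seq_along(test), function(i) {
      f(matrix(control, nrow = 1), matrix(test[-i], nrow = 1))
    }, numeric(1))
  )

  used <- method
  ci <- NULL
  if (method == "bca") {
    ci <- bca_ci(boot_dist, est, jack, alpha)
    if (is.null(ci)) used <- "percentile"  # fall back
  }
  if (is.null(ci)) ci <- pct_ci(boot_dist, alpha)
  new_effect_size(est, ci, length(control), length(test), B, alpha, used,
                  statistic, boot_dist)
}

#' Bootstrap mean difference between two groups
#'
#' The unpaired mean difference `mean(test) - mean(control)` with a
#' bias-corrected-and-accelerated (BCa) bootstrap confidence interval, the
#' statistic shown under a Gardner-Altman plot. Groups are resampled
#' independently. When the acceleration is undefined (all jackknife values
#' equal) the percentile interval is used and recorded in `method`.
#'
#' @param control,test Numeric vectors (>= 3 finite values each).
#' @param B Bootstrap resamples (>= 1000; default 5000).
#' @param alpha Two-sided miscoverage (0.05 for a 95% CI).
#' @param method `"bca"` (default) or `"percentile"`.
#' @param seed Integer seed.
#' @return An `effect_size` object; see [tidy()] / [glance()].
#' @export
#' @examples
#' mean_difference(c(1, 2, 3), c(2, 3, 4), seed = 1)
mean_difference <- function(control, test, B = 5000, alpha = 0.05,
                            method = c("bca", "percentile"), seed = 1L) {
  method <- match.arg(method)
  two_group_effect(control, test,
                   f = function(cm, tm) rowMeans(tm) - rowMeans(cm),
                   statistic = "mean_difference",
                   B = B, alpha = alpha, method = method, seed = seed)
}

#' Bootstrap percent-of-control summary
#'
#' `100 * mean(test) / mean(control)` with a bootstrap CI; the plus-minus
#' form often quoted alongside (e.g. "90% +/- 8%") is the CI half-width,
#' returned in `half_width`.
#'
#' @inheritParams mean_difference
#' @return An `effect_size` (percent units) with extra element `half_width`.
#' @export
percent_of_control <- function(control, test, B = 5000, alpha = 0.05,
                               method = c("bca", "percentile"), seed = 1L) {
  method <- match.arg(method)
  if (mean(control[is.finite(control)]) <= 0) {
    abort("`control` must have positive mean.")
  }
  out <- two_group_effect(control, test,
                          f = function(cm, tm) 100 * rowMeans(tm) / rowMeans(cm),
                          statistic = "percent_of_control",
                          B = B, alpha = alpha, method = method, seed = seed)
  out$half_width <- (out$ci_high - out$ci_low) / 2
  out
}

#' Hatch-rate summary across replicates
#'
#' Percent viable eggs per replicate plus the across-replicate mean and
#' standard deviation.
#'
#' @param viable_counts,total_counts Integer vectors, one entry per
#'   replicate; `0 <= viable <= total`, `total > 0`.
#' @return A list with `per_replicate` (tibble: `replicate`, `viable`,
#'   `total`, `percent_viable`), `mean_percent`, `sd_percent`.
#' @export
#' @examples
#' hatch_summary(c(50, 70), c(100, 100))
hatch_summary <- function(viable_counts, total_counts) {
  if (length(viable_counts) != length(total_counts)) {
    abort("viable and total counts must have equal length.")
  }
  if (any(total_counts <= 0)) abort("Replicates with total = 0 are invalid.")
  if (any(viable_counts < 0 | viable_counts > total_counts)) {
    abort("Require 0 <= viable <= total in every replicate.")
  }
  pct <- 100 * viable_counts / total_counts
  list(
    per_replicate = tibble::tibble(
      replicate = seq_along(pct), viable = viable_counts,
      total = total_counts, percent_viable = pct
    ),
    mean_percent = mean(pct),
    sd_percent = if (length(pct) > 1) sd(pct) else NA_real_
  )
}
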