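#' Fit a three-parameter logistic growth curve to one animal
#'
#' Least-squares fit of `L(t) = l_max / (1 + exp(-rate * (t - shift)))` to a
#' length-versus-time series (Levenberg-Marquardt). Starting values come
#' from the data: `l_max` from the maximum observed length, `shift` from the
#' time of steepest smoothed increase, and `rate` from the maximal slope via
#' the logistic identity `max slope = rate * l_max / 4`.
#'
#' @param trajectory Data frame with columns `time_h` and `length_um`
#'   (missing lengths allowed and dropped).
#' @param bounds Optional list with `lower`/`upper` numeric vectors of
#'   length 3 (order: l_max, rate, shift).
#' @return An object of class `logistic_fit`: list with `l_max_um`,
#'   `rate_per_h`, `shift_h`, `rss`, `converged`, `n_points`, and the
#'   underlying `nls` fit. Use [tidy()] / [glance()] for tabular access.
#' @export
#' @examples
#' tr <- gen_growth_series(noise_sd = 0, seed = 1)$trajectory
#' fit_logistic(tr)
fit_logistic <- function(trajectory, bounds = NULL) {
  stopifnot(all(c("time_h", "length_um") %in% names(trajectory)))
  ok <- is.finite(trajectory$time_h) & is.finite(trajectory$length_um)
  t <- trajectory$time_h[ok]
  y <- trajectory$length_um[ok]
  if (length(t) < 8) abort("Need >= 8 non-missing points to fit.")
  if (diff(range(t)) < 10) abort("Points must span >= 10 h.")
  if (diff(range(y)) == 0) abort("degenerate trajectory: constant lengths")

  # smoothed slope for initialization
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  sl <- diff(as.numeric(ys)) / diff(t)
  i_max <- which.max(sl)
  l_max0 <- 1.05 * max(y)
  shift0 <- (t[i_max] + t[i_max + 1]) / 2
  rate0 <- max(4 * max(sl) / l_max0, 1e-3)

  lower <- bounds$lower %||% c(l_max = 1e-8, rate = 1e-6, shift = min(t) - 50)
  upper <- bounds$upper %||% c(l_max = 10 * max(y), rate = 100,
                               shift = max(t) + 50)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ l_max / (1 + exp(-rate * (t - shift))),
      start = list(l_max = l_max0, rate = rate0, shift = shift0),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- list(l_max_um = l_max0, rate_per_h = rate0, shift_h = shift0,
                rss = sum((y - l_max0 / (1 + exp(-rate0 * (t - shift0))))^2),
                converged = FALSE, n_points = length(t), fit = NULL)
  } else {
    cf <- coef(fit)
    out <- list(l_max_um = unname(cf["l_max"]),
                rate_per_h = unname(cf["rate"]),
                shift_h = unname(cf["shift"]),
                rss = sum(resid(fit)^2),
                converged = fit$convInfo$isConv %||% TRUE,
                n_points = length(t), fit = fit)
  }
  structure(out, class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> l_max = %.4g um, rate = %.4g /h, shift = %.4g h (rss %.4g, %s)\n",
    x$l_max_um, x$rate_per_h, x$shift_h, x$rss,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("l_max_um", "rate_per_h", "shift_h"),
    estimate = c(x$l_max_um, x$rate_per_h, x$shift_h)
  )
}

#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged, n_points = x$n_points)
}

#' Fit logistic growth curves to a whole cohort
#'
#' @param trajectories Data frame with `animal_id`, `time_h`, `length_um`.
#' @param ... Passed to [fit_logistic()].
#' @return A tibble with one row per animal: parameter estimates, `rss`,
#'   `converged` (animals whose fit errors are dropped with a warning).
#' @export
fit_logistic_cohort <- function(trajectories, ...) {
  split_tr <- split(trajectories, trajectories$animal_id)
  rows <- purrr::imap(split_tr, function(tr, id) {
    f <- tryCatch(fit_logistic(tr, ...), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    tibble::tibble(animal_id = id, l_max_um = f$l_max_um,
                   rate_per_h = f$rate_per_h, shift_h = f$shift_h,
                   rss = f$rss, converged = f$converged)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) warn(sprintf("%d animal(s) could not be fit.", dropped))
  dplyr::bind_rows(rows)
}

#' Median growth curve with a bootstrap confidence band
#'
#' Per-animal trajectories are linearly interpolated onto a common time
#' grid; at each grid point the across-animal median is reported with a
#' percentile bootstrap confidence interval of the median (resampling
#' animals with replacement).
#'
#' @param trajectories Data frame with `animal_id`, `time_h`, `length_um`.
#' @param time_grid Numeric grid (hours); default spans the data at 1 h.
#' @param B Bootstrap resamples.
#' @param alpha Two-sided miscoverage level (0.05 gives a 95% interval).
#' @param min_animals Minimum animals contributing for a grid point to be
#'   reported.
#' @param seed Integer seed.
#' @return Tibble: `time_h`, `median_um`, `ci_low`, `ci_high`, `n_animals`.
#' @export
median_curve <- function(trajectories, time_grid = NULL, B = 1000,
                         alpha = 0.05, min_animals = 3, seed = 1L) {
  ids <- unique(trajectories$animal_id)
  if (is.null(time_grid)) {
    time_grid <- seq(floor(min(trajectories$time_h)),
                     ceiling(max(trajectories$time_h)), by = 1)
  }
  interp <- vapply(ids, function(id) {
    tr <- trajectories[trajectories$animal_id == id, ]
    approx(tr$time_h, tr$length_um, xout = time_grid, rule = 1)$y
  }, numeric(length(time_grid)))
  interp <- matrix(interp, nrow = length(time_grid))

  n_contrib <- rowSums(!is.na(interp))
  med <- apply(interp, 1, median, na.rm = TRUE)
  med[n_contrib < min_animals] <- NA_real_

  n_anim <- length(ids)
  cis <- with_seed(seed, {
    boot_meds <- matrix(NA_real_, B, length(time_grid))
    for (b in seq_len(B)) {
      pick <- sample.int(n_anim, n_anim, replace = TRUE)
      boot_meds[b, ] <- apply(interp[, pick, drop = FALSE], 1,
                              median, na.rm = TRUE)
    }
    apply(boot_meds, 2, function(v) {
      v <- v[is.finite(v)]
      if (length(v) == 0) c(NA_real_, NA_real_) else pct_ci(v, alpha)
    })
  })
  tibble::tibble(
    time_h = time_grid,
    median_um = med,
    ci_low = ifelse(is.na(med), NA_real_, cis[1, ]),
    ci_high = ifelse(is.na(med), NA_real_, cis[2, ]),
    n_animals = n_contrib
  )
}

#' Developmental interval arithmetic from event times
#'
#' From per-animal egg-laid, hatch and first-egg times computes ex-utero
#' development (laid to hatch), larval development (hatch to first egg) and
#' generation time (laid to first egg). Missing events propagate to the
#' intervals that need them; out-of-order events reject the record.
#'
#' @param events Data frame with columns `t_laid_h`, `t_hatch_h`,
#'   `t_first_egg_h` (any may be `NA`); extra columns (e.g. `animal_id`)
#'   are carried through.
#' @return The input plus `ex_utero_h`, `larval_h`, `generation_h`.
#' @export
#' @examples
#' extract_timings(data.frame(t_laid_h = 0, t_hatch_h = 12,
#'                            t_first_egg_h = 60))
extract_timings <- function(events) {
  req <- c("t_laid_h", "t_hatch_h", "t_first_egg_h")
  stopifnot(all(req %in% names(events)))
  with(events, {
    if (any(!is.na(t_laid_h) & !is.na(t_hatch_h) & t_hatch_h <= t_laid_h) ||
        any(!is.na(t_hatch_h) & !is.na(t_first_egg_h) &
            t_first_egg_h <= t_hatch_h) ||
        any(!is.na(t_laid_h) & !is.na(t_first_egg_h) &
            t_first_egg_h <= t_laid_h)) {
      abort("out-of-order developmental events: require t_laid < t_hatch < t_first_egg")
    }
  })
  dplyr::mutate(
    tibble::as_tibble(events),
    ex_utero_h = .data$t_hatch_h - .data$t_laid_h,
    larval_h = .data$t_first_egg_h - .data$t_hatch_h,
    generation_h = .data$t_first_egg_h - .data$t_laid_h
  )
}

#' Windowed bootstrap of between-group length ratios
#'
#' Developmental time is tiled into `n_windows` half-open windows of
#' `window_len_h` hours starting at `start_h` (defaults: 15 windows of
#' 4 h 16 min tiling \[0, 64 h\]). Within each window, `B` bootstrap ratios
#' are formed by drawing one measurement uniformly with replacement from
#' each group; a draw whose two measurement times differ by more than
#' `max_dt_h` is rejected and redrawn (attempt cap `100 * B` per window).
#' The ratio is oriented `length_b / length_a` (test over control). Each
#' window reports the mean ratio and the percentile interval of the
#' accepted draws.
#'
#' @param group_a,group_b Data frames with `time_h`, `length_um`
#'   (measurement-level pooling across animals; group_a is the reference,
#'   e.g. wild type).
#' @param window_len_h Window length in hours (default 4 h 16 min).
#' @param n_windows Number of windows.
#' @param start_h Start of the first window.
#' @param max_dt_h Maximal real-time difference between the two measurements
#'   of a ratio.
#' @param B Bootstrap samples per window.
#' @param alpha Two-sided miscoverage for the percentile interval.
#' @param seed Integer seed.
#' @return Tibble with one row per window: `window_index` (0-based),
#'   `t_start_h`, `t_end_h`, `mean_ratio`, `ci_low`, `ci_high`,
#'   `n_accepted`, `n_rejected`. Windows where no admissible pair exists
#'   (or either group is empty) have `n_accepted = 0` and `NA` statistics.
#' @export
windowed_ratio_bootstrap <- function(group_a, group_b,
                                     window_len_h = 4 + 16 / 60,
                                     n_windows = 15,
                                     start_h = 0,
                                     max_dt_h = 1.5,
                                     B = 1000,
                                     alpha = 0.05,
                                     seed = 1L) {
  stopifnot(all(c("time_h", "length_um") %in% names(group_a)),
            all(c("time_h", "length_um") %in% names(group_b)))
  edges <- start_h + window_len_h * (0:n_windows)
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_windows), function(w) {
      lo <- edges[w]
      hi <- edges[w + 1]
      ia <- group_a$time_h >= lo & group_a$time_h < hi &
        is.finite(group_a$length_um)
      ib <- group_b$time_h >= lo & group_b$time_h < hi &
        is.finite(group_b$length_um)
      ta <- group_a$time_h[ia]; la <- group_a$length_um[ia]
      tb <- group_b$time_h[ib]; lb <- group_b$length_um[ib]
      empty <- tibble::tibble(
        window_index = w - 1L, t_start_h = lo, t_end_h = hi,
        mean_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        n_accepted = 0L, n_rejected = 0L
      )
      if (length(ta) == 0 || length(tb) == 0) return(empty)
      ratios <- numeric(0)
      attempts <- 0L
      rejected <- 0L
      cap <- 100L * B
      while (length(ratios) < B && attempts < cap) {
        todo <- min(B - length(ratios) + 64L, cap - attempts)
        i <- sample.int(length(ta), todo, replace = TRUE)
        j <- sample.int(length(tb), todo, replace = TRUE)
        ok <- abs(ta[i] - tb[j]) <= max_dt_h
        attempts <- attempts + todo
        rejected <- rejected + sum(!ok)
        ratios <- c(ratios, (lb[j] / la[i])[ok])
      }
      if (length(ratios) < B) {
        # attempt cap exceeded before B admissible ratios: report empty
        empty$n_rejected <- rejected
        return(empty)
      }
      ratios <- ratios[seq_len(B)]
      ci <- pct_ci(ratios, alpha)
      tibble::tibble(
        window_index = w - 1L, t_start_h = lo, t_end_h = hi,
        mean_ratio = mean(ratios), ci_low = ci[1], ci_high = ci[2],
        n_accepted = length(ratios), n_rejected = rejected
      )
    })
  })
}
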