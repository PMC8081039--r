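#' Simulate a single-animal growth trajectory with developmental events
#'
#' Body length over developmental time follows the three-parameter logistic
#' `l_max / (1 + exp(-rate * (t - shift)))` with multiplicative Gaussian
#' measurement noise, sampled on a regular imaging grid (default one frame
#' every 3 minutes over 65 h, the cadence of long-term single-worm imaging
#' rigs). Egg-laid, hatch and first-egg times are attached as ground-truth
#' developmental events.
#'
#' @param l_max_um Asymptotic adult length in micrometres (> 0).
#' @param rate_per_h Logistic growth rate per hour (> 0).
#' @param shift_h Inflection time in hours.
#' @param t_end_h End of the recording, hours.
#' @param dt_min Sampling interval in minutes.
#' @param noise_sd Relative (multiplicative) measurement noise SD;
#'   `0.05` means 5% noise.
#' @param t_hatch_h,t_first_egg_h Event times in hours; must satisfy
#'   `0 <= t_hatch_h < t_first_egg_h <= t_end_h`.
#' @param animal_id Identifier carried in the output.
#' @param seed Integer seed.
#'
#' @return A list with `trajectory` (tibble: `animal_id`, `time_h`,
#'   `length_um`), `events` (tibble: `animal_id`, `t_laid_h`, `t_hatch_h`,
#'   `t_first_egg_h`) and `truth` (the generating parameters).
#' @export
gen_growth_series <- function(l_max_um = 1000,
                              rate_per_h = 0.12,
                              shift_h = 30,
                              t_end_h = 65,
                              dt_min = 3,
                              noise_sd = 0.05,
                              t_hatch_h = 12,
                              t_first_egg_h = 60,
                              animal_id = "animal1",
                              seed = 1L) {
  assert_scalar_num(l_max_um, "l_max_um")
  if (l_max_um <= 0) abort("`l_max_um` must be > 0.")
  assert_scalar_num(rate_per_h, "rate_per_h", positive = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  if (!(0 <= t_hatch_h && t_hatch_h < t_first_egg_h &&
        t_first_egg_h <= t_end_h)) {
    abort("Require 0 <= t_hatch_h < t_first_egg_h <= t_end_h.")
  }

  times <- seq(0, t_end_h, by = dt_min / 60)
  mu <- l_max_um / (1 + exp(-rate_per_h * (times - shift_h)))
  lengths <- if (noise_sd > 0) {
    with_seed(seed, mu * (1 + rnorm(length(mu), sd = noise_sd)))
  } else {
    mu
  }

  list(
    trajectory = tibble::tibble(
      animal_id = animal_id, time_h = times, length_um = lengths
    ),
    events = tibble::tibble(
      animal_id = animal_id, t_laid_h = 0,
      t_hatch_h = t_hatch_h, t_first_egg_h = t_first_egg_h
    ),
    truth = list(l_max_um = l_max_um, rate_per_h = rate_per_h,
                 shift_h = shift_h, noise_sd = noise_sd)
  )
}

#' Simulate a cohort of growth trajectories
#'
#' Draws per-animal logistic parameters around cohort-level means and
#' concatenates the resulting trajectories, emulating a multi-well
#' single-worm imaging run.
#'
#' @param n_animals Number of animals.
#' @param l_max_um,rate_per_h,shift_h Cohort mean parameters.
#' @param cv Between-animal coefficient of variation applied to each
#'   parameter.
#' @param prefix Prefix for animal ids.
#' @inheritParams gen_growth_series
#' @return A list with `trajectories` (one tibble, all animals), `events`,
#'   and `truth` (per-animal parameter tibble).
#' @export
gen_growth_cohort <- function(n_animals = 20,
                              l_max_um = 1000,
                              rate_per_h = 0.12,
                              shift_h = 30,
                              cv = 0.05,
                              t_end_h = 65,
                              dt_min = 3,
                              noise_sd = 0.05,
                              prefix = "wt",
                              seed = 1L) {
  pars <- with_seed(seed, tibble::tibble(
    animal_id = sprintf("%s_%03d", prefix, seq_len(n_animals)),
    l_max_um = l_max_um * (1 + rnorm(n_animals, sd = cv)),
    rate_per_h = rate_per_h * (1 + rnorm(n_animals, sd = cv)),
    shift_h = shift_h * (1 + rnorm(n_animals, sd = cv)),
    t_hatch_h = pmax(0, 12 + rnorm(n_animals, sd = 1)),
    t_first_egg_h = pmin(t_end_h, 60 + rnorm(n_animals, sd = 1)),
    sub_seed = sample.int(1e6, n_animals)
  ))
  sims <- purrr::pmap(pars, function(animal_id, l_max_um, rate_per_h, shift_h,
                                     t_hatch_h, t_first_egg_h, sub_seed) {
    gen_growth_series(l_max_um, rate_per_h, shift_h, t_end_h, dt_min,
                      noise_sd, t_hatch_h, t_first_egg_h,
                      animal_id = animal_id, seed = sub_seed)
  })
  list(
    trajectories = dplyr::bind_rows(purrr::map(sims, "trajectory")),
    events = dplyr::bind_rows(purrr::map(sims, "events")),
    truth = pars[, setdiff(names(pars), "sub_seed")]
  )
}
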