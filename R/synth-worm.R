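#' Simulate a single-worm microscopy image with known centerline length
#'
#' Renders one bright, sinuous larva on a dark background by sweeping a disk
#' of diameter `thickness_px` along a parametric sine centerline whose arc
#' length is solved numerically to match `arclength_um`. The analytic arc
#' length of the generating curve is returned as ground truth, so length
#' estimators can be scored without any manual annotation. A linear
#' background gradient and additive Gaussian noise emulate uneven
#' transmitted-light illumination and camera noise.
#'
#' @param arclength_um True centerline arc length in micrometres (> 0).
#' @param px_size_um Pixel size in micrometres per pixel.
#' @param amplitude_um Amplitude of the sinusoidal body posture, in
#'   micrometres. `0` gives a straight worm.
#' @param period_um Spatial period of the undulation, in micrometres.
#' @param thickness_px Body thickness (disk diameter) in pixels, >= 1.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise on the
#'   \[0, 1\] intensity scale.
#' @param gradient Peak-to-peak amplitude of the linear background ramp.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#'
#' @return A list with components `image` (a [worm_image()]) and `truth`, a
#'   list with `centerline_length_um`, `centerline` (n x 2 matrix of row/col
#'   pixel coordinates), `mask` (logical matrix) and `px_size_um`.
#' @export
#' @examples
#' w <- gen_worm_image(210, seed = 1)
#' w$truth$centerline_length_um
gen_worm_image <- function(arclength_um,
                           px_size_um = 1,
                           amplitude_um = 15,
                           period_um = 130,
                           thickness_px = 7,
                           noise_sd = 0.02,
                           gradient = 0.05,
                           seed = 1L) {
  assert_scalar_num(arclength_um, "arclength_um", positive = TRUE)
  assert_scalar_num(px_size_um, "px_size_um", positive = TRUE)
  assert_scalar_num(amplitude_um, "amplitude_um", nonneg = TRUE)
  assert_scalar_num(thickness_px, "thickness_px")
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  if (thickness_px < 1) abort("`thickness_px` must be >= 1.")
  if (arclength_um < 2 * px_size_um) {
    abort("`arclength_um` must span at least 2 pixels at this pixel size.")
  }

  A <- amplitude_um
  P <- period_um
  # speed along the curve y = A sin(2*pi*x/P), parameterized by x
  dsdx <- function(x) sqrt(1 + (A * 2 * pi / P * cos(2 * pi * x / P))^2)
  arclen <- function(X) {
    if (X <= 0) return(0)
    stats::integrate(dsdx, 0, X, rel.tol = 1e-10)$value
  }
  if (A == 0) {
    x_end <- arclength_um
  } else {
    x_end <- stats::uniroot(function(X) arclen(X) - arclength_um,
                            lower = arclength_um / (1 + (A * 2 * pi / P)^2),
                            upper = arclength_um, tol = 1e-9)$root
  }
  true_len <- if (A == 0) arclength_um else arclen(x_end)

  # densely sampled centerline in um, then in pixel coordinates
  xs <- seq(0, x_end, by = px_size_um / 4)
  ys <- A * sin(2 * pi * xs / P)

  r <- thickness_px / 2
  margin <- ceiling(r) + 4L
  col_px <- xs / px_size_um + margin + 1
  row_px <- (ys - min(ys)) / px_size_um + margin + 1
  nrow_img <- ceiling(max(row_px)) + margin
  ncol_img <- ceiling(max(col_px)) + margin

  mask <- matrix(FALSE, nrow_img, ncol_img)
  rr <- ceiling(r)
  offs <- expand.grid(dr = -rr:rr, dc = -rr:rr)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2, , drop = FALSE]
  for (k in seq_along(col_px)) {
    ri <- round(row_px[k]) + offs$dr
    ci <- round(col_px[k]) + offs$dc
    keep <- ri >= 1 & ri <= nrow_img & ci >= 1 & ci <= ncol_img
    mask[cbind(ri[keep], ci[keep])] <- TRUE
  }

  img <- with_seed(seed, {
    ramp <- matrix(rep(seq(0, gradient, length.out = ncol_img),
                       each = nrow_img), nrow_img, ncol_img)
    base <- 0.15 + ramp
    base[mask] <- 0.85
    noisy <- base + rnorm(length(base), sd = noise_sd)
    matrix(pmin(pmax(noisy, 0), 1), nrow_img, ncol_img)
  })

  list(
    image = worm_image(img, px_size_um),
    truth = list(
      centerline_length_um = true_len,
      centerline = cbind(row = row_px, col = col_px),
      mask = mask,
      px_size_um = px_size_um
    )
  )
}

#' Simulate a batch of worm images spanning a length range
#'
#' Convenience wrapper around [gen_worm_image()] drawing per-worm true
#' lengths, postures and noise from ranges typical of L1-stage larvae.
#'
#' @param n Number of worms.
#' @param length_range_um Range from which true lengths are drawn uniformly.
#' @param seed Integer seed.
#' @param px_size_um,thickness_px,noise_sd Passed to [gen_worm_image()].
#' @return A tibble with columns `worm_id`, `true_length_um`, and a
#'   list-column `image` of [worm_image()] objects.
#' @export
gen_worm_batch <- function(n = 100,
                           length_range_um = c(150, 300),
                           px_size_um = 1,
                           thickness_px = 7,
                           noise_sd = 0.02,
                           seed = 1L) {
  pars <- with_seed(seed, {
    tibble::tibble(
      worm_id = sprintf("worm%03d", seq_len(n)),
      true_length_um = runif(n, length_range_um[1], length_range_um[2]),
      amplitude_um = runif(n, 0, 25),
      period_um = runif(n, 90, 180),
      sub_seed = sample.int(1e6, n)
    )
  })
  pars$image <- purrr::pmap(
    list(pars$true_length_um, pars$amplitude_um, pars$period_um, pars$sub_seed),
    function(len, amp, per, s) {
      gen_worm_image(len, px_size_um = px_size_um, amplitude_um = amp,
                     period_um = per, thickness_px = thickness_px,
                     noise_sd = noise_sd, seed = s)$image
    }
  )
  pars[, c("worm_id", "true_length_um", "image")]
}
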