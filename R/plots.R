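# ggplot2 helpers for the main result types. All numbers shown are computed
# by the statistics functions, never inside the plotting code.

#' Plot median growth curves with confidence bands
#'
#' @param curves Named list of [median_curve()] tibbles (one per genotype)
#'   or a single tibble.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(curves) {
  if (is.data.frame(curves)) curves <- list(cohort = curves)
  df <- dplyr::bind_rows(curves, .id = "genotype")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$median_um,
                                   colour = .data$genotype,
                                   fill = .data$genotype)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Body length (µm)",
                  title = "Median growth curve (95% CI of the median)") +
    ggplot2::theme_minimal()
}

#' Gardner-Altman two-panel estimation plot
#'
#' Raw group values above, the bootstrap distribution of the effect size
#' with its confidence interval below.
#'
#' @param control,test Numeric vectors (the raw data).
#' @param effect An `effect_size` from [mean_difference()].
#' @param labels Length-2 group labels.
#' @return A ggplot object (two stacked panels via facetting).
#' @export
plot_gardner_altman <- function(control, test, effect,
                                labels = c("control", "test")) {
  raw <- tibble::tibble(
    group = factor(rep(labels, c(length(control), length(test))),
                   levels = labels),
    value = c(control, test),
    panel = "raw data"
  )
  boot <- tibble::tibble(value = effect$boot_dist, panel = "mean difference")
  raw$panel <- factor(raw$panel, c("raw data", "mean difference"))
  boot$panel <- factor(boot$panel, c("raw data", "mean difference"))
  ggplot2::ggplot() +
    ggplot2::geom_jitter(data = raw,
                         ggplot2::aes(x = .data$group, y = .data$value),
                         width = 0.1, alpha = 0.6) +
    ggplot2::geom_violin(data = boot,
                         ggplot2::aes(x = factor("difference"),
                                      y = .data$value), fill = "grey80") +
    ggplot2::annotate("pointrange", x = 1, y = effect$estimate,
                      ymin = effect$ci_low, ymax = effect$ci_high,
                      data = NULL) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s = %.3g, CI95 [%.3g, %.3g]",
                                  effect$statistic, effect$estimate,
                                  effect$ci_low, effect$ci_high)) +
    ggplot2::theme_minimal()
}

#' @method autoplot effect_size
#' @export
autoplot.effect_size <- function(object, ...) {
  boot <- tibble::tibble(value = object$boot_dist)
  ggplot2::ggplot(boot, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$estimate,
                                       object$ci_high),
                        linetype = c("dashed", "solid", "dashed")) +
    ggplot2::labs(x = object$statistic, y = "bootstrap count") +
    ggplot2::theme_minimal()
}

#' MA plot of differential-expression results
#'
#' @param de Tibble from [de_analysis()].
#' @return A ggplot object: log2 fold change versus log10 base mean, DE
#'   genes highlighted.
#' @export
plot_ma <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(x = log10(.data$base_mean + 0.5),
                                   y = .data$log2_fc,
                                   colour = .data$is_de)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "log10 mean normalized count",
                  y = "log2 fold change", colour = "DE") +
    ggplot2::theme_minimal()
}

#' @method autoplot wd_pca
#' @export
autoplot.wd_pca <- function(object, x = 1, y = 2, colour = NULL, ...) {
  df <- object$scores
  pcs <- names(df)[-1]
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[pcs[x]]],
                                        y = .data[[pcs[y]]])) +
    ggplot2::labs(
      x = sprintf("%s (%.2f)", pcs[x], object$explained[x]),
      y = sprintf("%s (%.2f)", pcs[y], object$explained[y])
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
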