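#' Plot per-cluster amplitude tuning curves
#'
#' @param tuning Output of [amplitude_tuning()] (optionally with extra
#'   grouping columns, e.g. `group` from [run_pipeline()]).
#' @return A ggplot.
#' @export
plot_tuning <- function(tuning) {
  ggplot2::ggplot(tuning,
                  ggplot2::aes(x = .data$amplitude_db, y = .data$mean_beta,
                               colour = factor(.data$cluster),
                               group = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "amplitude (dB re full scale)",
                  y = "mean regression coefficient",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot network density against amplitude, with the surrogate null
#'
#' @param metrics The `network_metrics.csv` table from [run_pipeline()]
#'   (`genotype`, `amplitude_db`, `density`, `null_density`).
#' @return A ggplot.
#' @export
plot_density_sweep <- function(metrics) {
  d <- tidyr::pivot_longer(metrics, c("density", "null_density"),
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$amplitude_db, y = .data$value,
                                  colour = .data$genotype,
                                  linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "amplitude (dB re full scale)", y = "network density",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Heat map of pairwise correlation versus distance
#'
#' @param binned Output of [bin_correlation_distance()].
#' @return A ggplot.
#' @export
plot_correlation_distance <- function(binned) {
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$dist_bin, y = .data$corr_bin,
                                       fill = log10(.data$n_pairs))) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "pair distance (µm)", y = "correlation",
                  fill = "log10 pairs") +
    ggplot2::theme_minimal()
}

#' @describeIn rentian Plot the box samples and the fitted power law.
#' @param object A `rent_fit` (must have been produced by [fit_rent()] on
#'   samples you still hold) -- pass the samples through `samples`.
#' @param samples The box samples the fit was computed from.
#' @param ... Ignored.
#' @export
autoplot.rent_fit <- function(object, samples, ...) {
  ok <- samples$n_inside >= 2 & samples$e_crossing >= 1
  d <- samples[ok, ]
  ggplot2::ggplot(d, ggplot2::aes(x = log(.data$n_inside),
                                  y = log(.data$e_crossing))) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$exponent,
                         colour = "red") +
    ggplot2::labs(x = "log nodes in box", y = "log boundary-crossing edges",
                  title = sprintf("Rent exponent %.3f ± %.3f",
                                  object$exponent, object$exponent_sd)) +
    ggplot2::theme_minimal()
}

#' Plot per-region decoding performance
#'
#' @param decode_tbl Output of [decode_cohort()].
#' @return A ggplot of per-subset validation r-squared by region and genotype.
#' @export
plot_decoding <- function(decode_tbl) {
  pathway <- c("ON", "rHB", "Cb", "TS", "Teg", "TeO", "Pr", "Th", "Ha", "Tel")
  d <- dplyr::mutate(decode_tbl,
                     region = factor(.data$region,
                                     levels = intersect(pathway, .data$region)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$r2,
                                  colour = .data$genotype)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = expression(validation ~ r^2)) +
    ggplot2::theme_minimal()
}
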