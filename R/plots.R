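#' Plot a binned spectrum on log-log axes
#'
#' Filled points are significant bins (when significance was flagged),
#' open points are not; error bars are the across-fold standard deviations.
#' Only positive bin means can be drawn on the log scale; negative means
#' are dropped from the panel (they are retained in the data).
#'
#' @param object A `binned_spectrum` from [aggregate_folds()] (optionally
#'   after [flag_significance()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binned_spectrum <- function(object, ...) {
  df <- as_tibble(object)
  df$significant <- if ("significant" %in% names(df)) df$significant else TRUE
  df <- dplyr::filter(df, .data$mean > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, .Machine$double.xmin),
                                        ymax = .data$mean + .data$sd), width = 0.05) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1), guide = "none") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank (bin center)", y = "cross-validated variance") +
    ggplot2::theme_classic()
}

#' Plot a spectral correlation table
#'
#' @param object A `spectral_correlation` from [spectral_correlation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectral_correlation <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$valid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center, y = .data$r)) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dotted") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$r - .data$sd,
                                        ymax = .data$r + .data$sd), width = 0.05) +
    ggplot2::geom_point(ggplot2::aes(shape = !.data$flagged), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1), guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "rank (bin center)", y = "spectral correlation r") +
    ggplot2::theme_classic()
}

#' Plot permutation-null percentile envelopes
#'
#' Gray envelopes at the 68th/95th/99th percentiles of the permutation
#' null; overlay an observed spectrum with
#' `+ ggplot2::geom_point(data = ...)`.
#'
#' @param object A `null_ensemble` from [build_null_ensemble()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.null_ensemble <- function(object, ...) {
  df <- tidyr::pivot_longer(object$bins, c("p68", "p95", "p99"),
                            names_to = "percentile", values_to = "value")
  df <- dplyr::filter(df, .data$value > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center, y = .data$value,
                                   group = .data$percentile)) +
    ggplot2::geom_line(ggplot2::aes(linewidth = .data$percentile), colour = "grey55") +
    ggplot2::scale_linewidth_manual(values = c(p68 = 0.3, p95 = 0.6, p99 = 0.9),
                                    guide = "none") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank (bin center)", y = "null spectrum percentile") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
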