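#' Plot an R_split convergence curve
#'
#' Log-log R_split versus pattern count, one line per simulated condition.
#'
#' @param object an `sfx_rsplit_curve` tibble from
#'   [convergence_experiment()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sfx_rsplit_curve <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      condition = sprintf("bw %.2g%%, conv %.2g mrad",
                                          100 * .data$bandwidth,
                                          1000 * .data$convergence))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_patterns,
                                   y = 100 * .data$r_split,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "patterns merged", y = "R_split (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the hit-rate time series
#'
#' @param series tibble from [hit_rate_series()].
#' @return a ggplot object.
#' @export
plot_hit_rate <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$block, y = .data$hit_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "frame block", y = "hit rate") +
    ggplot2::theme_minimal()
}

#' Plot cell-parameter histograms
#'
#' @param hist_tbl tibble from [cell_parameter_histograms()].
#' @return a ggplot object (faceted by parameter).
#' @export
plot_cell_histograms <- function(hist_tbl) {
  ggplot2::ggplot(hist_tbl, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "patterns") +
    ggplot2::theme_minimal()
}

#' Plot a peak list over the frame footprint
#'
#' @param peaks tibble from [find_peaks()].
#' @return a ggplot object.
#' @export
plot_peaks <- function(peaks) {
  ggplot2::ggplot(peaks, ggplot2::aes(x = .data$fast, y = .data$slow,
                                      size = .data$intensity)) +
    ggplot2::geom_point(shape = 1, colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "fast (px)", y = "slow (px)") +
    ggplot2::theme_minimal()
}
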