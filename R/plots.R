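# ggplot2 visualisations for the main result types.

#' @export
autoplot.vm_traces <- function(object, cells = NULL, ...) {
  df <- tidy(object)
  if (!is.null(cells)) df <- dplyr::filter(df, .data$cell %in% cells)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$vm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~cell, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "time (s)", y = "Vm (mV)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sliding_corr <- function(object, ...) {
  df <- tidyr::expand_grid(lag = object$lag, time = object$time)
  df$r <- as.vector(object$correlogram)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$lag, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "time (s)", y = "lag (s)", fill = "R") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phase_hist <- function(object, ...) {
  mids <- (object$breaks_deg[-1] + object$breaks_deg[-length(object$breaks_deg)]) / 2
  df <- tibble(phase = mids, count = object$counts)
  ggplot2::ggplot(df, ggplot2::aes(.data$phase, .data$count)) +
    ggplot2::geom_col(width = diff(object$breaks_deg)[1], fill = "steelblue") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::geom_vline(xintercept = object$preferred_phase_deg,
                        colour = "red") +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 270, by = 90)) +
    ggplot2::labs(x = "phase (deg)", y = "spike count") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cpg_stm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lag * 1000)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$null_mean - 2 * .data$null_sd,
      ymax = .data$null_mean + 2 * .data$null_sd), fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_mean), colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$z), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "lag (ms)", y = "z-scored median Vm") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.motif_comparison <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$fast_r, fill = .data$motif)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.5) +
    ggplot2::labs(x = "pairwise fast correlation", y = "pairs") +
    ggplot2::theme_minimal()
}

#' Decoupling scatter of slow vs fast pairwise correlation
#'
#' Plots each pair's fast-component correlation against its slow-component
#' correlation with the unity line; decoupling (sparse or actively
#' decorrelated input) appears as points hugging fast R = 0 across the
#' full slow-R range.
#'
#' @param pairs Tibble from [vm_pair_correlations()].
#' @return A ggplot.
#' @export
plot_decoupling <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(.data$slow_r, .data$fast_r)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "orange") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_cartesian(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "slow correlation (rate modulation)",
                  y = "fast correlation (synaptic input)") +
    ggplot2::theme_minimal()
}
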