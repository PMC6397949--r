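#' Plot a motion-energy trace with detected blinks
#'
#' @param object An [me_series()].
#' @param events Optional [detect_blinks()] tibble to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot me_series
#' @export
autoplot.me_series <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "motion energy") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_point(
      data = events, ggplot2::aes(x = .data$time_s, y = .data$height),
      color = "red", size = 1.2
    )
  }
  p
}

#' Plot a noise-contribution-ratio spectrum
#'
#' Both directional NCR curves against frequency.
#'
#' @param object A [compute_ncr()] spectrum.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ncr_spectrum
#' @export
autoplot.ncr_spectrum <- function(object, ...) {
  if (!"ncr_y_to_x" %in% names(object)) {
    abort("spectrum lacks NCR columns; run compute_ncr().")
  }
  long <- tidyr::pivot_longer(
    object[, c("freq_hz", "ncr_y_to_x", "ncr_x_to_y")],
    c("ncr_y_to_x", "ncr_x_to_y"),
    names_to = "direction", values_to = "ncr"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$freq_hz, y = .data$ncr, color = .data$direction
  )) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "frequency (Hz)", y = "NCR") +
    ggplot2::theme_minimal()
}

#' Plot a synchronization map as a z histogram
#'
#' @param object A [voxelwise_sync()] map.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sync_map
#' @export
autoplot.sync_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::labs(x = "Fisher z", y = "voxels") +
    ggplot2::theme_minimal()
}

#' Box-and-point plot of participant-level integrated NCR by quantity
#'
#' @param sigma_tbl The `sigma_ncr` tibble of a [run_behavioral()] result
#'   (columns `quantity`, `sigma_ncr`).
#' @return A ggplot.
#' @export
plot_sigma_ncr <- function(sigma_tbl) {
  ggplot2::ggplot(sigma_tbl, ggplot2::aes(
    x = .data$quantity, y = .data$sigma_ncr
  )) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = expression(Sigma * "NCR (Hz)")) +
    ggplot2::theme_minimal()
}
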