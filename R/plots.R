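#' Plot a current trace
#'
#' @param object A [blm_trace()].
#' @param events Optional event tibble; detected windows are shaded.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.blm_trace <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$current_pA)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::labs(x = "time (s)", y = "current (pA)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = events,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
        ymin = -Inf, ymax = Inf, fill = .data$class_label),
      alpha = 0.2, inherit.aes = FALSE
    ) + ggplot2::labs(fill = "class")
  }
  p
}

#' Per-class conductance distributions
#'
#' @param events Labelled event tibble.
#' @param which `"mean"` or `"peak"` conductance.
#' @return A ggplot of overlaid density histograms by class.
#' @export
plot_conductance_distribution <- function(events, which = c("mean", "peak")) {
  which <- match.arg(which)
  col <- if (which == "mean") "mean_conductance_pS" else "peak_conductance_pS"
  ggplot2::ggplot(events,
    ggplot2::aes(.data[[col]], fill = .data$class_label)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.6, position = "identity") +
    ggplot2::labs(x = paste(which, "conductance (pS)"), y = "events",
      fill = "class") +
    ggplot2::theme_minimal()
}

#' Lifetime distributions by class
#'
#' @param events Labelled event tibble.
#' @return A ggplot of log-scaled lifetime histograms by class.
#' @export
plot_lifetimes <- function(events) {
  ggplot2::ggplot(events,
    ggplot2::aes(.data$lifetime_ms, fill = .data$class_label)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.6, position = "identity") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lifetime (ms)", y = "events", fill = "class") +
    ggplot2::theme_minimal()
}

#' Particle z-height histogram
#'
#' @param stats A `blm_height_stats` from [height_stats()].
#' @return A ggplot of the height histogram with the mean marked.
#' @export
plot_height_histogram <- function(stats) {
  stopifnot(inherits(stats, "blm_height_stats"))
  ggplot2::ggplot(stats$histogram,
    ggplot2::aes(.data$bin_mid_nm, .data$count)) +
    ggplot2::geom_col(width = diff(stats$histogram$bin_mid_nm[1:2]) * 0.9) +
    ggplot2::geom_vline(xintercept = stats$mean_nm, linetype = 2) +
    ggplot2::labs(x = "z-height (nm)", y = "particles") +
    ggplot2::theme_minimal()
}
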