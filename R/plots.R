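# ggplot2 graphics for simulated runs, amplification curves and standard
# curves.

channel_colours <- c(green = "#1b9e77", yellow = "#e6ab02",
                     orange = "#d95f02", red = "#d73027")

#' Plot a simulated run's fluorescence traces and switch points
#'
#' @param object A `pcr_run` from [simulate_run()].
#' @param channels Channels to show (default: all present).
#' @param ... Unused.
#' @return A ggplot: fluorescence vs time per channel, with melt (dashed)
#'   and anneal (dotted) switch points overlaid.
#' @export
autoplot.pcr_run <- function(object, channels = NULL, ...) {
  tr <- object$traces
  if (!is.null(channels)) tr <- dplyr::filter(tr, .data$channel %in% channels)
  ggplot2::ggplot(tr, ggplot2::aes(.data$time_s, .data$value,
                                   colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(
      data = object$switch_points,
      ggplot2::aes(xintercept = .data$time_s, linetype = .data$kind),
      colour = "grey40", alpha = 0.6, linewidth = 0.2
    ) +
    ggplot2::scale_colour_manual(values = channel_colours) +
    ggplot2::scale_linetype_manual(values = c(melt_switch = "dashed",
                                              anneal_switch = "dotted")) +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)",
                  colour = "channel", linetype = "switch") +
    ggplot2::theme_minimal()
}

#' Plot a normalized amplification curve with its Cq
#'
#' @param object A `normalized_curve` from [normalize_curve()].
#' @param cq Optional `cq_result` to annotate.
#' @param ... Unused.
#' @return A ggplot of normalized fluorescence vs cycle.
#' @export
autoplot.normalized_curve <- function(object, cq = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$cycle, .data$value)) +
    ggplot2::geom_line(colour = "#1b9e77") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "cycle", y = "normalized fluorescence (0-100)") +
    ggplot2::theme_minimal()
  if (!is.null(cq) && isTRUE(cq$positive)) {
    p <- p + ggplot2::geom_vline(xintercept = cq$cq, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Plot a standard curve
#'
#' @param object A `standard_curve` from [standard_curve()].
#' @param ... Unused.
#' @return A ggplot of mean Cq (+/- SD) vs log10 concentration with the
#'   fitted regression line and the derived efficiency in the subtitle.
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$log10_conc, .data$mean_cq)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_cq - .data$sd_cq,
                   ymax = .data$mean_cq + .data$sd_cq),
      width = 0.1, na.rm = TRUE
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#d95f02") +
    ggplot2::labs(
      x = "log10 concentration (copies/uL)", y = "Cq",
      subtitle = sprintf("slope %.3f cycles/decade, efficiency %.2f, r^2 %.4f",
                         object$slope, object$efficiency, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
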