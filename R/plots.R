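# ggplot2 displays for the result types. Speeds are shown in mm/s and
# depths in um, the units of the measurements being emulated.

#' Plot a velocity trace
#'
#' @param object An `onb_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.onb_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$speed * 1e3)) +
    ggplot2::geom_point(shape = 15, size = 1, colour = "grey20") +
    ggplot2::labs(x = "time (s)", y = "speed (mm/s)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot a transient fit over its data
#'
#' Data points with the fitted decay curve, the measured-trace-and-model
#' display used for power-resolved velocity traces.
#'
#' @param object An `onb_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.onb_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$speed * 1e3),
                        shape = 15, size = 1, colour = "grey20") +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted * 1e3),
                       colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = "time (s)", y = "speed (mm/s)") +
    ggplot2::theme_minimal()
}

#' Plot a depth profile
#'
#' Treated densities by depth with the baseline band (mean +/- 2 sd of the
#' control densities).
#'
#' @param object An `onb_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.onb_profile <- function(object, ...) {
  tr <- profile_treated(object)
  base <- profile_baseline(object)
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$depth_um,
                                        y = .data$density_au))
  if (length(base) >= 2L) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = mean(base) - 2 * sd(base),
                               ymax = mean(base) + 2 * sd(base),
                               alpha = 0.15, fill = "steelblue") +
      ggplot2::geom_hline(yintercept = mean(base), linetype = 2,
                          colour = "steelblue")
  }
  p + ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "grey30") +
    ggplot2::labs(x = "depth from bladder wall (um)",
                  y = "raw integrated density (au)") +
    ggplot2::theme_minimal()
}

#' Plot a power-sweep analysis
#'
#' Peak speed against power fraction on log-log axes with the fitted
#' power law.
#'
#' @param object An `onb_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.onb_sweep <- function(object, ...) {
  tab <- object$table
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$power_fraction,
                                         y = .data$peak_speed * 1e3)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "power fraction", y = "peak speed (mm/s)",
                  subtitle = sprintf("gamma = %.3f, %s", object$gamma,
                                     object$verdict)) +
    ggplot2::theme_minimal()
  if (is.finite(object$gamma)) {
    ref <- tab$peak_speed[nrow(tab)] *
      (tab$power_fraction / tab$power_fraction[nrow(tab)])^object$gamma
    p <- p + ggplot2::geom_line(ggplot2::aes(y = ref * 1e3),
                                colour = "red", linetype = 2)
  }
  p
}
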