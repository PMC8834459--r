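#' Plot a time-normalised kick cycle
#'
#' Position (x/y/z) and resultant-velocity curves per marker over the
#' normalized cycle, with the support/contact phase boundary marked at 65%.
#'
#' @param object A [kick_cycle()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kick_cycle <- function(object, ...) {
  long <- object$curves %>%
    tidyr::pivot_longer(c("X", "Y", "Z", "speed"), names_to = "quantity",
                        values_to = "value") %>%
    mutate(quantity = factor(.data$quantity,
                             levels = c("X", "Y", "Z", "speed"),
                             labels = c("x (m)", "y (m)", "z (m)",
                                        "speed (m/s)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$percent, y = .data$value,
                                     colour = .data$marker)) +
    ggplot2::geom_vline(xintercept = 65.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "kick cycle (%)", y = NULL,
                  title = sprintf("Kick cycle: %s", object$curves$trial[1]),
                  subtitle = "dashed line: support/contact boundary (65%)") +
    ggplot2::theme_minimal()
}

#' Plot method-comparison median curves with 95% CI bands
#'
#' Pointwise medians and confidence bands of two methods' normalized curves
#' for one marker and quantity, mirroring the time-series comparison
#' figures of method-agreement studies.
#'
#' @param manual,automatic Curve tibbles (`trial`, `marker`, `percent`,
#'   value columns).
#' @param marker Marker to plot.
#' @param quantity Column to plot (default `"speed"`).
#' @return A ggplot object.
#' @export
plot_method_bands <- function(manual, automatic, marker,
                              quantity = "speed") {
  band <- function(curves, label) {
    df <- filter(curves, .data$marker == !!marker) %>%
      arrange(.data$trial, .data$percent)
    m <- matrix(df[[quantity]], nrow = dplyr::n_distinct(df$trial),
                byrow = TRUE)
    median_ci_curves(m) %>% mutate(percent = .data$point - 1, method = label)
  }
  both <- bind_rows(band(manual, "manual"), band(automatic, "automatic"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$percent, y = .data$median,
                                     colour = .data$method,
                                     fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "kick cycle (%)", y = quantity,
                  title = sprintf("%s: median and 95%% CI", marker)) +
    ggplot2::theme_minimal()
}

#' Plot the phase-resolved MAE table of an agreement report
#'
#' @param object An [compare_methods()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_report <- function(object, ...) {
  long <- object$mae %>%
    filter(.data$marker != "overall") %>%
    tidyr::pivot_longer(c("X", "Y", "Z", "All", "VEL"), names_to = "axis",
                        values_to = "mae")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$marker, y = .data$mae,
                                     fill = .data$phase)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "MAE (cm; VEL m/s)",
                  title = "Method-agreement MAE by marker and phase") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
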