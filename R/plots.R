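#' Plot centre-of-mass energy traces
#'
#' Time course of potential, kinetic and total CoM energy, optionally with
#' vertical lines at the heel-strike (step transition) times, mirroring the
#' standard representation of pendulum-like exchange.
#'
#' @param energies Energy table from [com_energies()] (columns `time`,
#'   `e_p`, `e_k`, `e_tot`).
#' @param events Optional [gait_events()] whose heel strikes are drawn as
#'   dashed step boundaries.
#' @return A ggplot object.
#' @export
plot_energy_series <- function(energies, events = NULL) {
  long <- tidyr::pivot_longer(energies, c("e_p", "e_k", "e_tot"),
                              names_to = "component", values_to = "energy")
  long$component <- factor(long$component, c("e_p", "e_k", "e_tot"),
                           c("E[P]", "E[K]", "E[TOT]"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$energy,
                                          colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "energy (J)", colour = NULL) +
    ggplot2::scale_colour_manual(
      values = c("E[P]" = "#1b7837", "E[K]" = "#762a83", "E[TOT]" = "grey30"),
      labels = scales_parse_labels()) +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    hs <- sort(c(events$heel_strikes$left, events$heel_strikes$right))
    p <- p + ggplot2::geom_vline(xintercept = hs, linetype = "dashed",
                                 colour = "grey60")
  }
  p
}

scales_parse_labels <- function() function(l) parse(text = l)

#' Ensemble plot of time-normalized step energy curves
#'
#' @param curves Long table from [normalized_energy_curves()].
#' @return A ggplot object: per-step traces with the ensemble mean.
#' @export
plot_step_ensemble <- function(curves) {
  long <- tidyr::pivot_longer(curves, c("e_p", "e_k"),
                              names_to = "component", values_to = "energy")
  ggplot2::ggplot(long, ggplot2::aes(.data$pct, .data$energy,
                                     group = interaction(.data$step_index,
                                                         .data$component),
                                     colour = .data$component)) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$component),
                          fun = mean, geom = "line", linewidth = 1.1) +
    ggplot2::labs(x = "step cycle (%)", y = "energy (J)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a stroke-group correlation with the healthy reference
#'
#' Reproduces the standard correlation panel: stroke-group subjects as
#' points with a linear fit, and the healthy group's mean +/- SD as a
#' reference marker.
#'
#' @param study A [run_study()] result.
#' @param x Subject-level column on the x axis (e.g. `"double_support"`).
#' @param y Subject-level column on the y axis (default `"eri_pct"`).
#' @return A ggplot object.
#' @export
plot_correlation_scatter <- function(study, x, y = "eri_pct") {
  subj <- study$subjects
  sg <- subj[subj$group == "stroke", ]
  hg <- subj[subj$group == "healthy", ]
  p <- ggplot2::ggplot(sg, ggplot2::aes(.data[[x]], .data[[y]])) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey20") +
    ggplot2::theme_minimal()
  if (nrow(hg)) {
    ref <- data.frame(x = mean(hg[[x]]), y = mean(hg[[y]]),
                      xsd = sd(hg[[x]]), ysd = sd(hg[[y]]))
    p <- p +
      ggplot2::geom_errorbar(data = ref,
                             ggplot2::aes(x = .data$x, y = .data$y,
                                          ymin = .data$y - .data$ysd,
                                          ymax = .data$y + .data$ysd),
                             colour = "red", width = 0, inherit.aes = FALSE) +
      ggplot2::geom_errorbarh(data = ref,
                              ggplot2::aes(y = .data$y,
                                           xmin = .data$x - .data$xsd,
                                           xmax = .data$x + .data$xsd),
                              colour = "red", height = 0, inherit.aes = FALSE) +
      ggplot2::geom_point(data = ref, ggplot2::aes(.data$x, .data$y),
                          colour = "red", size = 2, inherit.aes = FALSE)
  }
  p
}
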