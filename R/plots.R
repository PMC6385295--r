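# ggplot2 visualizations for the main result types.

#' @describeIn simulate_sck Plot a sensorgram with injection boundaries.
#' @param object An `allo_sensorgram`.
#' @param ... Unused.
#' @export
autoplot.allo_sensorgram <- function(object, ...) {
  sched <- attr(object, "schedule")
  p <- ggplot(object, aes(x = .data$time, y = .data$response)) +
    geom_line(color = "steelblue") +
    labs(x = "Time (s)", y = "Response (RU)",
         title = "Single-cycle kinetics sensorgram") +
    theme_minimal()
  if (!is.null(sched)) {
    p <- p + ggplot2::geom_vline(xintercept = sched$start[-1],
                                 linetype = "dotted", color = "grey60")
  }
  p
}

#' @describeIn fit_sck Plot data and fitted 1:1 model.
#' @param object An `sck_fit`.
#' @export
autoplot.sck_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$time)) +
    geom_point(aes(y = .data$response), size = 0.3, alpha = 0.4) +
    geom_line(aes(y = .data$fitted), color = "firebrick") +
    labs(x = "Time (s)", y = "Response (RU)",
         title = sprintf("1:1 fit: ka = %.3g /M/s, kd = %.3g /s, KD = %.3g M",
                         object$estimate["ka"], object$estimate["kd"],
                         object$KD)) +
    theme_minimal()
}

#' @describeIn fit_langmuir Plot the titration and fitted isotherm.
#' @param object A `langmuir_fit`.
#' @export
autoplot.langmuir_fit <- function(object, ...) {
  grid <- tibble(concentration = exp(seq(
    log(min(object$data$concentration[object$data$concentration > 0])),
    log(max(object$data$concentration)), length.out = 200)))
  grid$signal <- object$estimate["Bmax"] * grid$concentration /
    (object$estimate["KD"] + grid$concentration)
  ggplot(object$data, aes(x = .data$concentration, y = .data$signal)) +
    geom_point() +
    geom_line(data = grid, color = "firebrick") +
    ggplot2::scale_x_log10() +
    labs(x = "Concentration (M)", y = "Signal",
         title = sprintf("Langmuir isotherm: KD = %.3g M",
                         object$estimate["KD"])) +
    theme_minimal()
}

#' @describeIn epitope_footprint Plot epitope positions and their segments.
#' @param object An `allo_footprint`.
#' @param ... Unused.
#' @export
autoplot.allo_footprint <- function(object, ...) {
  epi <- filter(object$epitope, .data$role == "hla_alpha" |
                  is.na(.data$role))
  ggplot() +
    geom_segment(data = object$segments,
                 aes(x = .data$start - 0.4, xend = .data$end + 0.4,
                     y = 1, yend = 1, color = factor(.data$segment)),
                 linewidth = 4, alpha = 0.5) +
    geom_point(data = epi, aes(x = .data$position, y = 1), size = 2) +
    labs(x = "Alpha-chain position (mature numbering)", y = NULL,
         color = "Segment",
         title = "Epitope footprint segments") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    theme_minimal()
}

#' Plot cytotoxicity replicates by condition
#'
#' @param data Output of [cytotoxicity()] (columns `condition`,
#'   `cytotoxicity`).
#' @return A ggplot.
#' @export
plot_cytotoxicity <- function(data) {
  ggplot(data, aes(x = .data$condition, y = .data$cytotoxicity)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey80",
                          color = "grey30", width = 0.6) +
    geom_point(position = ggplot2::position_jitter(width = 0.08, height = 0),
               size = 2, alpha = 0.8) +
    labs(x = NULL, y = "Cytotoxicity (%)") +
    theme_minimal()
}
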