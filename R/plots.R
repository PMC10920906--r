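#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Dot plot of a repeat comparison
#'
#' Mimics the field's standard presentation: one dot per biological repeat
#' (normalized value), a line at the condition mean and error bars of one
#' standard deviation, with paired repeats sharing a colour.
#'
#' @param object a [compare_conditions()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot repeat_comparison
#' @export
autoplot.repeat_comparison <- function(object, ...) {
  df <- object$per_repeat
  stats <- dplyr::summarise(dplyr::group_by(df, .data$condition),
                            mean = mean(.data$normalized),
                            sd = stats::sd(.data$normalized),
                            .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$normalized)) +
    ggplot2::geom_errorbar(
      data = stats,
      ggplot2::aes(x = .data$condition, y = .data$mean,
                   ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2, inherit.aes = FALSE) +
    ggplot2::geom_crossbar(
      data = stats,
      ggplot2::aes(x = .data$condition, y = .data$mean,
                   ymin = .data$mean, ymax = .data$mean),
      width = 0.35, inherit.aes = FALSE) +
    ggplot2::geom_point(
      ggplot2::aes(colour = factor(.data$biological_repeat)), size = 3) +
    ggplot2::labs(x = NULL, y = paste0("normalized ", object$measure_name),
                  colour = "repeat",
                  subtitle = sprintf("%s, t = %.3g, p = %.3g %s",
                                     object$test, object$statistic,
                                     object$p_value, object$stars)) +
    ggplot2::theme_classic()
}

#' Plot MSD profiles against lag time
#'
#' @param object an `msd_profile` from [compute_msd()].
#' @param ... unused.
#' @return A ggplot object (per-trajectory profiles drawn faintly, the
#'   ensemble profile emphasised when present).
#' @method autoplot msd_profile
#' @export
autoplot.msd_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$is_ensemble <- df$trajectory_id == "ensemble"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_s, y = .data$msd_um2,
                                   group = .data$trajectory_id)) +
    ggplot2::geom_line(data = df[!df$is_ensemble, ], alpha = 0.25) +
    ggplot2::geom_line(data = df[df$is_ensemble, ], linewidth = 1.2,
                       colour = "firebrick") +
    ggplot2::labs(x = "lag time (s)",
                  y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_classic()
}

#' Histogram of flow-cytometry intensities with the derived gate
#'
#' @param samples event tibble (`sample_id`, `intensity`).
#' @param gate threshold from [derive_gate()], drawn as a vertical line.
#' @return A ggplot object on a log10 intensity scale.
#' @export
plot_flow_gate <- function(samples, gate = NULL) {
  p <- ggplot2::ggplot(samples,
                       ggplot2::aes(x = .data$intensity,
                                    fill = .data$sample_id)) +
    ggplot2::geom_histogram(bins = 100, alpha = 0.5,
                            position = "identity") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "fluorescence intensity (a.u.)", y = "events") +
    ggplot2::theme_classic()
  if (!is.null(gate)) {
    p <- p + ggplot2::geom_vline(xintercept = gate, linetype = "dashed")
  }
  p
}
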