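#' Plot trajectories
#'
#' @param tracks tibble with `track_id`, `x_um`, `y_um`.
#' @return a ggplot; y is reversed to match image coordinates (origin top
#'   left, y downward).
#' @export
plot_tracks <- function(tracks) {
  check_columns(tracks, c("track_id", "frame", "x_um", "y_um"), "tracks")
  ggplot2::ggplot(tracks, ggplot2::aes(.data$x_um, .data$y_um,
                                       group = .data$track_id,
                                       colour = factor(.data$track_id))) +
    ggplot2::geom_path(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram bar plot of a motility distribution
#'
#' @param object a `motility_histogram` tibble from [speed_histogram()] or
#'   [angle_histogram()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot motility_histogram
#' @export
autoplot.motility_histogram <- function(object, ...) {
  var <- attr(object, "variable") %||% "value"
  xlab <- switch(var,
                 speed = "instantaneous speed (µm/s)",
                 dtheta = "directional change (rad/frame)",
                 var)
  ggplot2::ggplot(object, ggplot2::aes(.data$bin_mid, .data$freq)) +
    ggplot2::geom_col(width = object$bin_right[1] - object$bin_left[1],
                      fill = "steelblue", colour = "grey30",
                      linewidth = 0.2) +
    ggplot2::labs(x = xlab, y = "frequency")
}

#' Plot condition-level motility summaries
#'
#' Mean +- SD (across replicate videos) of speed, and of directional change
#' when present, against exposure time, one line per Ag+ concentration.
#'
#' @param summary tibble from [summarize_condition()].
#' @return a ggplot.
#' @export
plot_motility_summary <- function(summary) {
  check_columns(summary, c("ag_conc", "exposure_min", "mean_speed"), "summary")
  long <- summary |>
    tidyr::pivot_longer(
      cols = dplyr::any_of(c("mean_speed", "mean_dtheta")),
      names_to = "stat", values_to = "mean"
    ) |>
    mutate(
      sd = ifelse(.data$stat == "mean_speed",
                  .data$sd_speed_across_reps,
                  .data$sd_dtheta_across_reps),
      stat = dplyr::recode(.data$stat,
                           mean_speed = "speed (µm/s)",
                           mean_dtheta = "directional change (rad/frame)")
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$exposure_min, .data$mean,
                                     colour = factor(.data$ag_conc))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::labs(x = "exposure time (min)", y = NULL,
                  colour = "Ag+ (µM)")
}

#' Plot a Gompertz fit
#'
#' Observed replicate curves with the fitted Gompertz curves overlaid.
#'
#' @param object a `gompertz_fit` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot gompertz_fit
#' @export
autoplot.gompertz_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(.data$time_hr, .data$od,
                                    group = .data$replicate)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted),
                       colour = "firebrick", na.rm = TRUE) +
    ggplot2::labs(x = "time (hr)", y = "OD750")
}

#' Plot a hormesis comparison
#'
#' Asymptote and lag time per condition with across-replicate SD bars;
#' hormetic conditions highlighted.
#'
#' @param report tibble from [compare_conditions()].
#' @return a ggplot.
#' @export
plot_hormesis <- function(report) {
  check_columns(report, c("condition", "A_mean", "lag_mean"), "report")
  long <- report |>
    tidyr::pivot_longer(cols = c("A_mean", "lag_mean"),
                        names_to = "stat", values_to = "mean") |>
    mutate(
      sd = ifelse(.data$stat == "A_mean", .data$A_sd, .data$lag_sd),
      stat = dplyr::recode(.data$stat, A_mean = "asymptote (OD750)",
                           lag_mean = "lag time (hr)"),
      flagged = ifelse(.data$stat == "asymptote (OD750)",
                       .data$hormetic_asymptote, .data$elongated_lag)
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$condition, .data$mean,
                                     fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::labs(x = "condition (µM Ag+)", y = NULL,
                  fill = "exceeds control\n+ combined SD")
}
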