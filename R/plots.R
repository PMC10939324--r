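# ggplot2 views of the main result types.

#' Plot a speed profile with its counted velocity peaks
#'
#' @param object A `reach_speed` tibble ([speed_profile()]).
#' @param amplitude_cutoff,min_separation Peak-counting parameters used to
#'   mark accepted peaks.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.reach_speed <- function(object, amplitude_cutoff = 0.020,
                                 min_separation = 0.150, ...) {
  ex <- alternating_extrema(object$speed)
  acc <- integer(0)
  last_t <- -Inf
  prev_min <- NA_real_
  for (j in seq_along(ex$value)) {
    if (ex$type[j] < 0L) prev_min <- ex$value[j]
    else if (!is.na(prev_min) && ex$value[j] - prev_min > amplitude_cutoff) {
      tj <- object$time[ex$index[j]]
      if (tj - last_t >= min_separation - 1e-9) {
        acc <- c(acc, ex$index[j]); last_t <- tj
      }
    }
  }
  peaks <- object[acc, ]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$speed)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(data = peaks, colour = "red", size = 2) +
    ggplot2::labs(x = "time (s)", y = "speed (m/s)",
                  title = sprintf("velocity profile (%d peaks)", length(acc))) +
    ggplot2::theme_minimal()
}

#' Plot per-condition kinematic summaries
#'
#' One panel per kinematic feature; points are participant-level condition
#' means, lines connect cell means, colour distinguishes ball modes.
#'
#' @param summaries Output of [summarize_features()] (stacked across
#'   participants).
#' @return A ggplot.
#' @export
plot_condition_summary <- function(summaries) {
  long <- tidyr::pivot_longer(
    summaries,
    dplyr::all_of(c("movement_time", "v_avg", "v_peak", "time_to_peak",
                    "n_peak")),
    names_to = "feature", values_to = "value"
  )
  long$cell <- factor(long$cell, levels = c("baseline", "TV", "TH", "TM"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell, y = .data$value,
                                     colour = .data$ball_mode)) +
    ggplot2::geom_point(alpha = 0.5,
                        position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$ball_mode),
                          fun = mean, geom = "line") +
    ggplot2::facet_wrap(~ feature, scales = "free_y") +
    ggplot2::labs(x = "condition", y = NULL, colour = "ball mode") +
    ggplot2::theme_minimal()
}

#' Plot per-muscle peak latencies across conditions
#'
#' @param latencies Latency table ([session_latencies()] stacked across
#'   participants).
#' @return A ggplot.
#' @export
plot_latencies <- function(latencies) {
  latencies$cell <- factor(latencies$cell,
                           levels = c("baseline", "TV", "TH", "TM"))
  ggplot2::ggplot(latencies,
                  ggplot2::aes(x = .data$cell, y = .data$latency,
                               colour = .data$ball_mode)) +
    ggplot2::geom_point(alpha = 0.5,
                        position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$ball_mode),
                          fun = mean, geom = "line") +
    ggplot2::facet_wrap(~ muscle) +
    ggplot2::labs(x = "condition", y = "peak latency (s)",
                  colour = "ball mode") +
    ggplot2::theme_minimal()
}
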