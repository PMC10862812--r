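#' Plot SSD staircase trajectories
#'
#' SSD against stop-trial index, one panel per modality — the standard visual
#' check that the tracker converges around the participant's race balance
#' point.
#'
#' @param events Simulated events tibble.
#' @return A ggplot.
#' @export
plot_staircase <- function(events) {
  d <- events |>
    filter(trial_type == "stop") |>
    group_by(modality) |>
    mutate(stop_idx = row_number()) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(stop_idx, ssd_ms, colour = outcome)) +
    ggplot2::geom_step(ggplot2::aes(group = 1), colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~modality) +
    ggplot2::labs(x = "Stop trial", y = "SSD (ms)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot condition-level normalized CSE
#'
#' Normalized CSE by stim time, colored by trial type, one panel per task;
#' baselines are shown as a dashed reference at 1.
#'
#' @param summary Output of [summarize_conditions()].
#' @return A ggplot.
#' @export
plot_condition_summary <- function(summary) {
  d <- summary |> filter(trial_type != "baseline")
  ggplot2::ggplot(d, ggplot2::aes(stim_time_ms, normalized_cse,
                                  colour = trial_type, group = trial_type)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~modality) +
    ggplot2::labs(x = "TMS stim time (ms)", y = "Normalized CSE",
                  colour = "Trial type") +
    ggplot2::theme_minimal()
}

#' Plot one EMG trace
#'
#' The raw trace with the pulse time marked and the MEP window shaded.
#'
#' @param traces An `emg_traces` object.
#' @param trial Trial index (matching `traces$meta$trial`).
#' @param window_ms MEP window to shade (ms after pulse).
#' @return A ggplot.
#' @export
plot_trace <- function(traces, trial, window_ms = c(10, 50)) {
  i <- match(trial, traces$meta$trial)
  if (is.na(i)) abort("Trial not found in traces.")
  sr <- traces$sampling_rate_hz
  t_ms <- (seq_len(ncol(traces$signal)) - 1) / sr * 1000
  pulse_ms <- (traces$meta$pulse_sample[i] - 1) / sr * 1000
  d <- tibble(t_ms = t_ms, value = traces$signal[i, ])
  ggplot2::ggplot(d, ggplot2::aes(t_ms, value)) +
    ggplot2::annotate("rect", xmin = pulse_ms + window_ms[1],
                      xmax = pulse_ms + window_ms[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = pulse_ms, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "Time (ms)", y = sprintf("EMG (%s)", traces$units),
                  title = sprintf("Trial %d", trial)) +
    ggplot2::theme_minimal()
}

#' Plot the suppression-category tabulation
#'
#' @param categories Output of [tabulate_categories()].
#' @return A ggplot.
#' @export
plot_categories <- function(categories) {
  ggplot2::ggplot(categories, ggplot2::aes(category, pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of participants") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
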