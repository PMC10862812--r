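#' Fit pause and cancel amplitudes to condition summaries
#'
#' Least-squares recovery of the two suppression amplitudes from the
#' per-cell normalized CSE means. With the bell peaks/widths and the
#' go-facilitation slope held at their generative values, the cell-mean model
#' is linear in the two amplitudes:
#' `cse = 1 + slope * E[t] * responding - pause_amp * b_p(s) * stop
#'        - cancel_amp * b_c(s) * stop * responding`,
#' where `s` is the probe's latency after the stop signal (the stim time, by
#' the probe scheduling), `b_p`/`b_c` are unit Gaussian bells, and `E[t]` is
#' the cell's mean probe latency from go onset (stim time on go trials,
#' mean SSD + stim time on stop trials). Baseline and failed-stop cells are
#' excluded.
#'
#' @param summary Output of [summarize_conditions()].
#' @param events The matching events tibble (for per-cell mean SSDs).
#' @param model A [pause_cancel_params()] supplying the fixed shape
#'   parameters (its amplitudes are ignored).
#' @param probed_modality Modality in which the probed muscle responds.
#' @return A `pause_cancel_fit` object with elements `estimates`
#'   (`pause_amp`, `cancel_amp`), `lm` (the underlying linear model), and
#'   `data` (the cell table with fitted values).
#' @seealso [generics::tidy()], [generics::glance()] methods.
#' @export
fit_suppression_amplitudes <- function(summary, events,
                                       model = pause_cancel_params(),
                                       probed_modality = "manual") {
  ssd_by_cell <- events |>
    filter(trial_type == "stop", outcome == "stop-success",
           tms_role == "task-pulse") |>
    group_by(modality, stim_time_ms) |>
    summarise(mean_ssd = mean(ssd_ms), .groups = "drop")

  cells <- summary |>
    filter(trial_type %in% c("go", "stop-success")) |>
    left_join(ssd_by_cell, by = c("modality", "stim_time_ms")) |>
    mutate(
      is_stop = trial_type == "stop-success",
      responding = modality == probed_modality,
      mean_t = ifelse(is_stop, mean_ssd + stim_time_ms, stim_time_ms),
      offset = 1 + model$go_facilitation_slope * mean_t * responding,
      x_pause = -is_stop * gauss_bell(stim_time_ms, 1, model$pause_peak_ms,
                                      model$pause_width_ms),
      x_cancel = -(is_stop & responding) *
        gauss_bell(stim_time_ms, 1, model$cancel_peak_ms,
                   model$cancel_width_ms),
      y = normalized_cse - offset
    )

  fit <- lm(y ~ 0 + x_pause + x_cancel, data = cells)
  cells$.fitted <- cells$offset + predict(fit)
  cells$.observed <- cells$normalized_cse
  structure(
    list(
      estimates = c(pause_amp = unname(coef(fit)["x_pause"]),
                    cancel_amp = unname(coef(fit)["x_cancel"])),
      lm = fit,
      data = cells
    ),
    class = "pause_cancel_fit"
  )
}

#' @export
print.pause_cancel_fit <- function(x, ...) {
  cat("<pause_cancel_fit>\n")
  cat(sprintf("  pause_amp  = %.4f\n", x$estimates["pause_amp"]))
  cat(sprintf("  cancel_amp = %.4f\n", x$estimates["cancel_amp"]))
  cat(sprintf("  cells = %d, residual SD = %.4g\n",
              nrow(x$data), summary(x$lm)$sigma))
  invisible(x)
}

#' Tidy a pause/cancel amplitude fit
#'
#' @param x A `pause_cancel_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @exportS3Method generics::tidy
tidy.pause_cancel_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble(
    term = c("pause_amp", "cancel_amp"),
    estimate = unname(x$estimates),
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' Glance at a pause/cancel amplitude fit
#'
#' @param x A `pause_cancel_fit`.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `sigma`, `nobs`.
#' @exportS3Method generics::glance
glance.pause_cancel_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble(r.squared = s$r.squared, sigma = s$sigma, nobs = nrow(x$data))
}

#' @exportS3Method ggplot2::autoplot
autoplot.pause_cancel_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .fitted, y = .observed,
                               colour = modality, shape = trial_type)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Fitted normalized CSE", y = "Observed normalized CSE",
                  colour = "Task", shape = "Trial type") +
    ggplot2::theme_minimal()
}
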