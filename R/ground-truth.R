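gauss_bell <- function(t, amp, peak, width) {
  amp * exp(-((t - peak)^2) / (2 * width^2))
}

#' Ground-truth CSE scaling under the pause-then-cancel model
#'
#' Returns the expected motor-evoked-potential scaling factor (relative to
#' active baseline) for a TMS probe at `probe_time_ms` after go-signal onset.
#' The responding effector (trial modality equal to the probed effector's
#' modality) gains linear go-related facilitation; on stop trials the Pause
#' bell suppresses any probed effector and the Cancel bell additionally
#' suppresses the responding effector, both time-locked to the stop signal at
#' `ssd_ms`. The result is floored at `model$floor`.
#'
#' All arguments except `model` are vectorized and recycled.
#'
#' @param trial_type `"go"` or `"stop"`.
#' @param modality Trial modality, `"manual"` or `"vocal"`.
#' @param ssd_ms Stop-signal delay (ms); ignored (may be `NA`) on go trials.
#' @param probe_time_ms Probe latency from go-signal onset (ms, `>= 0`).
#' @param model A [pause_cancel_params()].
#' @param probed_modality Modality in which the probed muscle responds
#'   (`"manual"` for the hand flexor probed here).
#' @return Numeric vector of scaling factors.
#' @export
#' @examples
#' m <- pause_cancel_params()
#' # responding effector, stop trial probed 250 ms after a 200 ms SSD:
#' cse_ground_truth("stop", "manual", 200, 450, m)
cse_ground_truth <- function(trial_type, modality, ssd_ms, probe_time_ms,
                             model = pause_cancel_params(),
                             probed_modality = "manual") {
  if (any(!is.finite(probe_time_ms)) || any(probe_time_ms < 0)) {
    abort("`probe_time_ms` must be finite and >= 0 (probes precede go onset are invalid).")
  }
  n <- max(length(trial_type), length(modality), length(ssd_ms),
           length(probe_time_ms))
  trial_type <- rep_len(trial_type, n)
  modality <- rep_len(modality, n)
  ssd_ms <- rep_len(ssd_ms, n)
  probe_time_ms <- rep_len(probe_time_ms, n)

  is_stop <- trial_type == "stop"
  if (any(is_stop & !is.finite(ssd_ms))) {
    abort("Stop trials need a finite `ssd_ms`.")
  }
  responding <- modality == probed_modality
  t_stop <- probe_time_ms - ssd_ms

  pause <- ifelse(is_stop,
                  gauss_bell(t_stop, model$pause_amp, model$pause_peak_ms,
                             model$pause_width_ms), 0)
  cancel <- ifelse(is_stop & responding,
                   gauss_bell(t_stop, model$cancel_amp, model$cancel_peak_ms,
                              model$cancel_width_ms), 0)
  fac <- ifelse(responding, model$go_facilitation_slope * probe_time_ms, 0)
  pmax(1 + fac - pause - cancel, model$floor)
}

#' Stop-related suppression components at matched probe times
#'
#' Convenience for inspecting the generative model: the suppression that the
#' Pause and Cancel bells contribute at a latency `t_after_stop_ms` after the
#' stop signal, i.e. the drop in scaling relative to a go probe at the same
#' moment (go facilitation cancels in that comparison).
#'
#' @param t_after_stop_ms Latency after stop-signal onset (ms).
#' @param model A [pause_cancel_params()].
#' @param responding Whether the probed effector is the responding one.
#' @return Numeric vector of suppression magnitudes.
#' @export
stop_suppression <- function(t_after_stop_ms, model = pause_cancel_params(),
                             responding = TRUE) {
  gauss_bell(t_after_stop_ms, model$pause_amp, model$pause_peak_ms,
             model$pause_width_ms) +
    if (responding) {
      gauss_bell(t_after_stop_ms, model$cancel_amp, model$cancel_peak_ms,
                 model$cancel_width_ms)
    } else 0
}
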