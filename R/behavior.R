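#' Detect vocal response onset from an amplitude envelope
#'
#' The response time is the time of the first sample strictly exceeding the
#' threshold, relative to go-signal onset (sample 1 = time 0). No crossing
#' means no response (`NA`).
#'
#' @param envelope Numeric amplitude envelope.
#' @param threshold_amp Detection threshold (same units as the envelope,
#'   `> 0`).
#' @param sampling_rate_hz Envelope sampling rate (Hz).
#' @return RT in ms, or `NA_real_` when no sample crosses the threshold.
#' @export
detect_voice_onset <- function(envelope, threshold_amp, sampling_rate_hz) {
  if (length(envelope) == 0) abort("`envelope` is empty.")
  if (any(!is.finite(envelope))) abort("`envelope` contains non-finite samples.")
  stopifnot(threshold_amp > 0)
  i <- which(envelope > threshold_amp)
  if (length(i) == 0) return(NA_real_)
  (i[1] - 1) / sampling_rate_hz * 1000
}

#' Detect vocal onsets for a whole session
#'
#' Applies [detect_voice_onset()] to every envelope. When `threshold_amp` is
#' `NULL` it is set to `noise_mult` times the RMS of the first 50 ms of all
#' envelopes (the pre-response noise floor), mirroring a "set amplitude"
#' criterion calibrated per session.
#'
#' @param envelopes A `voice_envelopes` object.
#' @param threshold_amp Fixed threshold, or `NULL` to derive one.
#' @param noise_mult Multiplier on the noise-floor RMS.
#' @return Tibble with `trial`, `rt_ms`.
#' @export
detect_voice_onsets <- function(envelopes, threshold_amp = NULL,
                                noise_mult = 5) {
  sr <- envelopes$sampling_rate_hz
  if (is.null(threshold_amp)) {
    k <- ms_to_samples(50, sr)
    threshold_amp <- noise_mult * sqrt(mean(envelopes$signal[, seq_len(k)]^2))
  }
  tibble(
    trial = envelopes$meta$trial,
    rt_ms = apply(envelopes$signal, 1, detect_voice_onset,
                  threshold_amp = threshold_amp, sampling_rate_hz = sr)
  )
}

#' Stop-signal reaction time by the integration method
#'
#' Go-trial omissions are appended to the go-RT distribution as the maximum
#' observed go RT (the consensus treatment in the stop-signal literature).
#' Go RTs are sorted ascending, the RT at rank
#' `ceiling(p_respond_given_signal * N)` is taken as the point where the
#' stopping process finishes, and SSRT is that RT minus the mean SSD.
#'
#' @param go_rts Responded go-trial RTs (ms); choice errors included.
#' @param omission_count Number of go omissions.
#' @param p_respond_given_signal Probability of responding on a stop trial,
#'   strictly inside (0, 1).
#' @param mean_ssd Mean stop-signal delay over all stop trials (ms).
#' @return SSRT (ms).
#' @export
#' @examples
#' compute_ssrt_integration(rep(500, 10), 0, 0.5, 300) # 200
compute_ssrt_integration <- function(go_rts, omission_count,
                                     p_respond_given_signal, mean_ssd) {
  go_rts <- go_rts[!is.na(go_rts)]
  if (length(go_rts) == 0) abort("Need at least one responded go trial.")
  if (!(p_respond_given_signal > 0 && p_respond_given_signal < 1)) {
    abort("`p_respond_given_signal` must lie strictly in (0, 1).")
  }
  rts <- sort(c(go_rts, rep(max(go_rts), omission_count)))
  nth <- rts[ceiling(p_respond_given_signal * length(rts))]
  nth - mean_ssd
}

#' Behavioral summary per modality
#'
#' Means over correct go trials and failed stops, p(inhibit), mean SSD over
#' all stop trials, omission rate, and SSRT by the integration method.
#'
#' @param events Simulated (or real, schema-matched) events tibble. A
#'   `participant` column, if present, is kept as an extra grouping level.
#' @return Tibble with one row per (participant x) modality: `mean_go_rt`,
#'   `mean_failed_stop_rt` (`NaN` when no stop failed), `p_inhibit`,
#'   `mean_ssd`, `ssrt`, `omission_rate`, and the trial counts behind them.
#' @export
summarize_behavior <- function(events) {
  if (!any(events$trial_type == "stop")) {
    abort("`events` contains no stop trials.")
  }
  groups <- intersect(c("participant", "modality"), names(events))
  events |>
    group_by(dplyr::across(dplyr::all_of(groups))) |>
    summarise(
      n_trials = n(),
      n_go = sum(trial_type == "go"),
      n_stop = sum(trial_type == "stop"),
      mean_go_rt = mean(rt_ms[outcome == "go-correct"]),
      mean_failed_stop_rt = mean(rt_ms[outcome == "stop-fail"]),
      p_inhibit = sum(outcome == "stop-success") / sum(trial_type == "stop"),
      mean_ssd = mean(ssd_ms[trial_type == "stop"]),
      omission_rate = sum(outcome == "go-omission") / sum(trial_type == "go"),
      ssrt = if (p_inhibit > 0 && p_inhibit < 1) {
        compute_ssrt_integration(
          rt_ms[trial_type == "go" & !is.na(rt_ms)],
          sum(outcome == "go-omission"),
          1 - p_inhibit,
          mean(ssd_ms[trial_type == "stop"])
        )
      } else NA_real_,
      .groups = "drop"
    )
}
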