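#' Locate the TMS pulse artifact
#'
#' Automated stand-in for per-trial visual verification: the pulse is taken as
#' the sample of maximum absolute deflection within `search_radius_ms` of the
#' scheduled pulse. The localization is flagged low-confidence when that
#' deflection is below `floor_mv` (e.g. a flat trace).
#'
#' @param trace Numeric EMG trace (mV).
#' @param expected_pulse_sample Scheduled pulse sample (1-based).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param search_radius_ms Search half-window (ms).
#' @param floor_mv Artifact detection floor (mV).
#' @return List with `pulse_sample` and `confident`.
#' @export
find_tms_artifact <- function(trace, expected_pulse_sample, sampling_rate_hz,
                              search_radius_ms = 5, floor_mv = 0.5) {
  r <- ms_to_samples(search_radius_ms, sampling_rate_hz)
  lo <- expected_pulse_sample - r
  hi <- expected_pulse_sample + r
  if (lo < 1 || hi > length(trace)) {
    abort("Artifact search window falls outside the trace.")
  }
  win <- trace[lo:hi]
  peak <- which.max(abs(win))
  list(pulse_sample = lo + peak - 1L, confident = abs(win[peak]) >= floor_mv)
}

#' Peak-to-peak MEP amplitude
#'
#' The MEP amplitude is the difference between the maximum and minimum
#' deflection in the window `window_ms` after the pulse (default 10-50 ms,
#' both endpoints included; times are converted to samples by rounding).
#'
#' @param trace Numeric EMG trace (mV).
#' @param pulse_sample Pulse sample (1-based).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param window_ms Length-2 window after the pulse (ms).
#' @return Amplitude in mV.
#' @export
extract_mep <- function(trace, pulse_sample, sampling_rate_hz,
                        window_ms = c(10, 50)) {
  i0 <- pulse_sample + ms_to_samples(window_ms[1], sampling_rate_hz)
  i1 <- pulse_sample + ms_to_samples(window_ms[2], sampling_rate_hz)
  if (i0 < 1 || i1 > length(trace)) {
    abort("MEP window falls outside the trace.")
  }
  win <- trace[i0:i1]
  max(win) - min(win)
}

#' Pre-pulse EMG root mean square
#'
#' RMS of the raw trace over the `span_ms` preceding the pulse (default
#' 80 ms), i.e. samples in `[pulse - span, pulse)`.
#'
#' @inheritParams extract_mep
#' @param span_ms Pre-pulse span (ms).
#' @return RMS in mV.
#' @export
prepulse_rms <- function(trace, pulse_sample, sampling_rate_hz, span_ms = 80) {
  i0 <- pulse_sample - ms_to_samples(span_ms, sampling_rate_hz)
  if (i0 < 1) abort("Pre-pulse span falls outside the trace.")
  sqrt(mean(trace[i0:(pulse_sample - 1L)]^2))
}

#' Measure MEPs for every TMS trial
#'
#' Runs artifact localization, peak-to-peak amplitude extraction and
#' pre-pulse RMS for each trace, returning one row per TMS trial.
#'
#' On paired-pulse trials the conditioning pulse (and its artifact) sits 2 ms
#' before the test pulse, so the pre-pulse RMS window is ended
#' `paired_gap_ms` before the test pulse to keep the measurement a measure of
#' muscle activity rather than stimulation artifact.
#'
#' @param traces An `emg_traces` object ([synthesize_traces()] or
#'   [read_traces()]).
#' @param window_ms MEP window after the pulse (ms).
#' @param prepulse_span_ms Pre-pulse RMS span (ms).
#' @param search_radius_ms Artifact search half-window (ms).
#' @param paired_gap_ms Gap between the end of the RMS window and the test
#'   pulse on paired-pulse trials (ms).
#' @return Tibble: `trial`, `pulse_time_ms` (trial coordinates, `NA` for
#'   baseline probes), `amplitude_mv`, `prepulse_rms_mv`,
#'   `artifact_confident`.
#' @export
measure_meps <- function(traces, window_ms = c(10, 50),
                         prepulse_span_ms = 80, search_radius_ms = 5,
                         paired_gap_ms = 4) {
  sr <- traces$sampling_rate_hz
  meta <- traces$meta
  paired <- if ("paired" %in% names(meta)) meta$paired else rep(FALSE, nrow(meta))
  n <- nrow(meta)
  amplitude <- rms <- numeric(n)
  confident <- logical(n)
  for (i in seq_len(n)) {
    trace <- traces$signal[i, ]
    art <- find_tms_artifact(trace, meta$pulse_sample[i], sr,
                             search_radius_ms)
    rms_ref <- art$pulse_sample -
      if (paired[i]) ms_to_samples(paired_gap_ms, sr) else 0L
    amplitude[i] <- extract_mep(trace, art$pulse_sample, sr, window_ms)
    rms[i] <- prepulse_rms(trace, rms_ref, sr, prepulse_span_ms)
    confident[i] <- art$confident
  }
  tibble(
    trial = meta$trial,
    pulse_time_ms = meta$pulse_time_ms,
    amplitude_mv = amplitude,
    prepulse_rms_mv = rms,
    artifact_confident = confident
  )
}
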