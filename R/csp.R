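moving_rms <- function(x, w) {
  # centred moving RMS; edges fall back to the partial window
  cs <- c(0, cumsum(x^2))
  n <- length(x)
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

first_run_start <- function(flag, min_len) {
  # index of the first TRUE-run of length >= min_len, else NA
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_len)
  if (length(ok) == 0) NA_integer_ else starts[ok[1]]
}

#' Detect the cortical silent period on one trace
#'
#' Automated stand-in for the analyst's judgment: after the MEP window, a
#' short centred moving-RMS envelope must first fall below `silence_frac` of
#' the pre-pulse tonic RMS for at least `min_silence_ms` (otherwise no CSP is
#' present), and the candidate resumption point is the start of the first
#' subsequent stretch of at least `hold_ms` where the envelope re-exceeds
#' `resume_frac` of the tonic level. The mark is then refined to the maximum
#' absolute deflection within +/-`refine_ms` of the candidate. Duration is
#' measured from the TMS pulse to the refined resumption point (absolute
#' silent-period convention). Traces whose tonic reference does not exceed
#' `noise_floor_mv` are flagged not-contracting (`present = FALSE`), as for
#' hand probes during the vocal task.
#'
#' @param trace Numeric EMG trace (mV).
#' @param pulse_sample Pulse sample (1-based).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param tonic_reference_rms Pre-pulse tonic RMS (mV), e.g. from
#'   [prepulse_rms()].
#' @param search_start_ms Start of the resumption search, after the pulse
#'   (ms); must clear the MEP.
#' @param env_window_ms Envelope window (ms). A short window keeps the
#'   resumption estimate sharp (a wide one smears the transition and biases
#'   the mark by several ms).
#' @param resume_frac Envelope fraction of tonic RMS counting as resumed.
#' @param silence_frac Envelope fraction of tonic RMS counting as silent.
#' @param hold_ms Minimum resumed stretch (ms).
#' @param min_silence_ms Minimum silent stretch for a CSP to exist (ms).
#' @param refine_ms Refinement half-window around the candidate mark (ms).
#' @param noise_floor_mv Tonic reference at or below this is not a
#'   contraction.
#' @return A one-row tibble: `present`, `resume_time_ms`, `duration_ms`,
#'   `flag` (`"ok"`, `"not-contracting"`, `"no-silence"`, `"no-resumption"`).
#' @export
detect_csp <- function(trace, pulse_sample, sampling_rate_hz,
                       tonic_reference_rms,
                       search_start_ms = 40,
                       env_window_ms = 5,
                       resume_frac = 0.5,
                       silence_frac = 0.25,
                       hold_ms = 5,
                       min_silence_ms = 20,
                       refine_ms = 2,
                       noise_floor_mv = 0.015) {
  sr <- sampling_rate_hz
  none <- function(flag) tibble(present = FALSE, resume_time_ms = NA_real_,
                                duration_ms = NA_real_, flag = flag)
  if (tonic_reference_rms <= noise_floor_mv) return(none("not-contracting"))

  from <- pulse_sample + ms_to_samples(search_start_ms, sr)
  if (from >= length(trace)) return(none("no-silence"))
  seg <- trace[from:length(trace)]
  env <- moving_rms(seg, max(3L, ms_to_samples(env_window_ms, sr)))

  silent <- env < silence_frac * tonic_reference_rms
  s0 <- first_run_start(silent, ms_to_samples(min_silence_ms, sr))
  if (is.na(s0)) return(none("no-silence"))

  active <- env >= resume_frac * tonic_reference_rms
  active[seq_len(s0)] <- FALSE
  c0 <- first_run_start(active, ms_to_samples(hold_ms, sr))
  if (is.na(c0)) return(none("no-resumption"))

  cand <- from + c0 - 1L
  # the envelope crossing leads the true resumption by up to half the
  # envelope window; sharpen the mark to the first raw deflection above the
  # resumption criterion in that neighbourhood (the analyst's mark)
  w <- max(3L, ms_to_samples(env_window_ms, sr))
  n0 <- max(cand - w, 1L)
  n1 <- min(cand + w, length(trace))
  raw_hit <- which(abs(trace[n0:n1]) > resume_frac * tonic_reference_rms)
  if (length(raw_hit) > 0) cand <- n0 + raw_hit[1] - 1L
  r <- ms_to_samples(refine_ms, sr)
  lo <- max(cand - r, 1L)
  hi <- min(cand + r, length(trace))
  resume <- lo + which.max(abs(trace[lo:hi])) - 1L

  dur <- (resume - pulse_sample) / sr * 1000
  tibble(present = TRUE,
         resume_time_ms = (resume - from + ms_to_samples(search_start_ms, sr)) / sr * 1000,
         duration_ms = dur, flag = "ok")
}

#' Measure silent periods for a session
#'
#' Runs [detect_csp()] on every eligible trace: single-pulse trials of the
#' probed (manual) task whose MEP passed the rejection filters — silent
#' periods are only scored on trials with a valid MEP. The tonic reference is
#' each trial's own pre-pulse RMS.
#'
#' @param traces An `emg_traces` object.
#' @param events Events tibble.
#' @param measurements Rejection-annotated measurements
#'   ([apply_rejection()] output).
#' @param ... Passed to [detect_csp()].
#' @return Tibble: `trial`, `present`, `resume_time_ms`, `duration_ms`,
#'   `flag`.
#' @export
measure_csps <- function(traces, events, measurements, ...) {
  ev <- events |> select(trial, modality, pulse_type)
  ok <- measurements |>
    left_join(ev, by = "trial") |>
    filter(!rejected, modality == "manual", pulse_type == "single")
  idx <- match(ok$trial, traces$meta$trial)
  rows <- purrr::map(seq_along(idx), function(j) {
    i <- idx[j]
    res <- detect_csp(traces$signal[i, ], traces$meta$pulse_sample[i],
                      traces$sampling_rate_hz, ok$prepulse_rms_mv[j], ...)
    dplyr::bind_cols(tibble(trial = ok$trial[j]), res)
  })
  bind_rows(rows)
}
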