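ms_to_samples <- function(ms, sr) as.integer(round(ms * sr / 1000))

# Discrete biphasic MEP (positive then negative half-sine), normalized so the
# sampled peak-to-peak amplitude is exactly `amp` regardless of sampling grid.
mep_waveform <- function(amp, duration_ms, sr) {
  k <- max(2L, ms_to_samples(duration_ms / 2, sr))
  lobe <- sin(pi * seq_len(k) / (k + 1))
  lobe <- lobe / max(lobe)
  amp / 2 * c(lobe, -lobe)
}

# Brief decaying stimulus artifact.
artifact_waveform <- function(amp, sr) {
  k <- max(2L, ms_to_samples(1.5, sr))
  amp * cos(pi * (seq_len(k) - 1)) * exp(-(seq_len(k) - 1) / (k / 2))
}

#' Synthesize one EMG trace
#'
#' Builds a single-trial EMG recording (mV): Gaussian recording noise, a
#' high-amplitude stimulus artifact at the pulse, a biphasic MEP whose sampled
#' peak-to-peak amplitude equals `mep_amp_mv` exactly, optionally a tonic
#' contraction background that falls silent from MEP offset until `csp_ms`
#' after the pulse, a voluntary response burst at `rt_ms`, and for
#' paired-pulse trials a conditioning-pulse artifact 2 ms before the test
#' pulse. Uses the current RNG state.
#'
#' @param n_samples Trace length in samples.
#' @param pulse_sample Test-pulse sample index (1-based).
#' @param mep_amp_mv Injected peak-to-peak MEP amplitude (mV); 0 omits the MEP.
#' @param synth A [trace_synth_params()].
#' @param tonic Add tonic background EMG (silent-period mode)?
#' @param csp_ms True silent-period duration, pulse to resumption (ms).
#' @param rt_ms Response time in trace coordinates (ms), or `NA`.
#' @param paired Paired-pulse trial?
#' @return Numeric vector of length `n_samples`.
#' @export
synth_emg_trace <- function(n_samples, pulse_sample, mep_amp_mv,
                            synth = trace_synth_params(),
                            tonic = FALSE, csp_ms = NA_real_,
                            rt_ms = NA_real_, paired = FALSE) {
  sr <- synth$sampling_rate_hz
  mep_end <- pulse_sample +
    ms_to_samples(synth$mep_latency_ms + synth$mep_duration_ms, sr)
  if (pulse_sample < 1 || mep_end > n_samples) {
    abort("Pulse (or its MEP window) falls outside the trace.")
  }

  x <- rnorm(n_samples, 0, synth$noise_rms_mv)

  if (tonic) {
    bg <- rnorm(n_samples, 0, synth$tonic_rms_mv)
    if (is.finite(csp_ms)) {
      silence_from <- pulse_sample +
        ms_to_samples(synth$mep_latency_ms + synth$mep_duration_ms, sr)
      resume_at <- pulse_sample + ms_to_samples(csp_ms, sr)
      resume_at <- max(resume_at, silence_from + 1L)
      bg[silence_from:min(resume_at - 1L, n_samples)] <- 0
    }
    x <- x + bg
  }

  if (!is.na(rt_ms)) {
    b0 <- ms_to_samples(rt_ms, sr) + 1L
    b1 <- min(b0 + ms_to_samples(250, sr), n_samples)
    if (b0 <= n_samples) {
      x[b0:b1] <- x[b0:b1] + rnorm(b1 - b0 + 1L, 0, synth$burst_rms_mv)
    }
  }

  art <- artifact_waveform(synth$artifact_amp_mv, sr)
  ai <- pulse_sample + seq_along(art) - 1L
  x[ai] <- art
  if (paired) {
    cart <- artifact_waveform(synth$artifact_amp_mv * 0.5, sr)
    ci <- pulse_sample - ms_to_samples(2, sr) + seq_along(cart) - 1L
    ci <- ci[ci >= 1]
    x[ci] <- cart[seq_along(ci)]
  }

  if (mep_amp_mv > 0) {
    wave <- mep_waveform(mep_amp_mv, synth$mep_duration_ms, sr)
    mi <- pulse_sample + ms_to_samples(synth$mep_latency_ms, sr) +
      seq_along(wave) - 1L
    x[mi] <- x[mi] + wave
  }
  x
}

#' Synthesize EMG traces for every TMS trial of a session
#'
#' For each events row carrying TMS, computes the ground-truth CSE scaling
#' under the pause-then-cancel model, derives the injected MEP amplitude
#' (`mep_base_amp_mv * scaling`, attenuated by the conditioning pulse on
#' paired trials) and the true silent-period duration, and renders the trace
#' with [synth_emg_trace()]. Task-pulse traces are in trial coordinates
#' (sample 1 = go-signal onset); baseline-probe traces are inter-trial
#' recordings with the pulse at `baseline_pulse_ms` and carry no response
#' activity. Tonic (silent-period) background is added on manual-modality
#' single-pulse trials, where the probed hand muscle is engaged by the task.
#'
#' @param events Simulated events tibble ([simulate_behavior()] output).
#' @param model A [pause_cancel_params()].
#' @param synth A [trace_synth_params()].
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @param probed_modality Modality in which the probed muscle responds.
#' @param baseline_pulse_ms Pulse position inside baseline-probe recordings.
#' @return An `emg_traces` object: list with `signal` (trials x samples
#'   matrix, mV), `meta` (tibble: `trial`, `pulse_sample`,
#'   `pulse_time_ms` — trial coordinates, `NA` for baseline probes),
#'   `truth` (every injected value per trial), `sampling_rate_hz`, `units`.
#' @export
synthesize_traces <- function(events,
                              model = pause_cancel_params(),
                              synth = trace_synth_params(),
                              seed = NULL,
                              probed_modality = "manual",
                              baseline_pulse_ms = 600) {
  run <- function() {
    tms <- events[events$tms_role != "none", , drop = FALSE]
    if (nrow(tms) == 0) abort("No TMS trials in `events`.")
    sr <- synth$sampling_rate_hz

    is_base <- tms$tms_role == "baseline-probe"
    is_stop <- tms$trial_type == "stop"
    paired <- !is.na(tms$pulse_type) & tms$pulse_type == "paired"
    tonic <- tms$modality == "manual" & !paired

    # trace-frame pulse time: trial time for task pulses, fixed for probes
    pulse_ms <- ifelse(is_base, baseline_pulse_ms, tms$tms_time_ms)
    duration_ms <- max(synth$trace_duration_ms, max(pulse_ms) + 400)
    n_samples <- ms_to_samples(duration_ms, sr) + 1L
    pulse_sample <- ms_to_samples(pulse_ms, sr) + 1L

    scaling <- rep(1, nrow(tms))
    task <- !is_base
    scaling[task] <- cse_ground_truth(
      tms$trial_type[task], tms$modality[task], tms$ssd_ms[task],
      tms$tms_time_ms[task], model, probed_modality
    )

    sici_frac <- ifelse(paired,
                        synth$sici_base_frac + synth$sici_stop_delta * is_stop,
                        0)
    # multiplicative trial-to-trial MEP variability, mean 1 (lognormal)
    jitter <- if (synth$mep_amp_cv > 0) {
      s <- sqrt(log(1 + synth$mep_amp_cv^2))
      exp(rnorm(nrow(tms), -s^2 / 2, s))
    } else rep(1, nrow(tms))
    mep_amp <- synth$mep_base_amp_mv * scaling * (1 - sici_frac) * jitter

    t_stop <- ifelse(is_stop & !is_base, tms$tms_time_ms - tms$ssd_ms, NA_real_)
    csp_true <- synth$csp_base_ms +
      ifelse(!is.na(t_stop),
             synth$csp_gain_ms *
               gauss_bell(t_stop, 1, model$cancel_peak_ms, model$cancel_width_ms),
             0) +
      if (synth$csp_sd_ms > 0) rnorm(nrow(tms), 0, synth$csp_sd_ms) else 0
    min_csp <- synth$mep_latency_ms + synth$mep_duration_ms + 10
    csp_true <- pmax(csp_true, min_csp)
    csp_true[!tonic] <- NA_real_
    # quantize to the sampling grid so truth matches what was injected
    csp_true <- ifelse(is.na(csp_true), NA_real_,
                       ms_to_samples(csp_true, sr) / sr * 1000)

    rt_trace <- ifelse(is_base, NA_real_, tms$rt_ms)

    signal <- matrix(0, nrow = nrow(tms), ncol = n_samples)
    for (i in seq_len(nrow(tms))) {
      signal[i, ] <- synth_emg_trace(
        n_samples, pulse_sample[i], mep_amp[i], synth,
        tonic = tonic[i], csp_ms = csp_true[i],
        rt_ms = rt_trace[i], paired = paired[i]
      )
    }

    structure(
      list(
        signal = signal,
        meta = tibble(
          trial = tms$trial,
          pulse_sample = pulse_sample,
          pulse_time_ms = ifelse(is_base, NA_real_, tms$tms_time_ms),
          paired = paired
        ),
        truth = tibble(
          trial = tms$trial,
          scaling = scaling,
          mep_amp_mv = mep_amp,
          sici_frac = sici_frac,
          tonic = tonic,
          csp_ms = csp_true,
          rt_ms = rt_trace
        ),
        sampling_rate_hz = sr,
        units = "mV"
      ),
      class = "emg_traces"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.emg_traces <- function(x, ...) {
  cat(sprintf("<emg_traces> %d trials x %d samples @ %g Hz (%s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate_hz, x$units))
  invisible(x)
}
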