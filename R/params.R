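#' Task design configuration
#'
#' Describes one session of the dual manual/vocal choice stop-signal task:
#' block structure, stop rate, TMS probe scheduling, and the adaptive
#' stop-signal-delay (SSD) staircase settings. The defaults reproduce the
#' single-pulse study design: 12 blocks of 90 trials (1080 trials), 1/3 stop
#' trials, TMS at 150/200/250 ms, inter-trial baseline probes at
#' 500/700/900 ms, SSD initialized at 200 ms and tracked in 50 ms steps with a
#' 1000 ms response window.
#'
#' @param n_blocks Number of task blocks; modality alternates across blocks.
#' @param trials_per_block Trials per block. `trials_per_block * stop_fraction`
#'   must be a whole number that is divisible by `length(stim_times_ms)` and by
#'   `length(baseline_probe_times_ms)` so pulse counts balance exactly.
#' @param stop_fraction Proportion of stop trials per block, in (0, 1).
#' @param modality_order `"manual-first"` or `"vocal-first"`.
#' @param stim_times_ms TMS probe latencies (ms). On go trials the latency is
#'   measured from go-signal onset; on stop trials from stop-signal onset.
#' @param baseline_probe_times_ms Latencies (ms after the preceding trial's
#'   end) of inter-trial-interval baseline probes.
#' @param paired_pulse If `TRUE`, single- and paired-pulse blocks alternate in
#'   pairs of blocks (the SICI design); otherwise all pulses are single.
#' @param ssd_init_ms,ssd_step_ms Staircase start value and step (ms).
#' @param response_window_ms Response deadline (ms).
#' @param seed RNG seed controlling the trial sequence (and, by default,
#'   downstream simulation).
#'
#' @return A `design_config` list.
#' @seealso [exp1_design()], [exp2_design()], [generate_trial_sequence()]
#' @export
#' @examples
#' cfg <- design_config(n_blocks = 1, trials_per_block = 9, seed = 1)
#' generate_trial_sequence(cfg)
design_config <- function(n_blocks = 12L,
                          trials_per_block = 90L,
                          stop_fraction = 1 / 3,
                          modality_order = c("manual-first", "vocal-first"),
                          stim_times_ms = c(150, 200, 250),
                          baseline_probe_times_ms = c(500, 700, 900),
                          paired_pulse = FALSE,
                          ssd_init_ms = 200,
                          ssd_step_ms = 50,
                          response_window_ms = 1000,
                          seed = 1L) {
  modality_order <- match.arg(modality_order)
  if (!(stop_fraction > 0 && stop_fraction < 1)) {
    abort("`stop_fraction` must lie in (0, 1).", class = "stopphys_invalid_design")
  }
  n_stop <- trials_per_block * stop_fraction
  if (abs(n_stop - round(n_stop)) > 1e-6) {
    abort("`trials_per_block * stop_fraction` must be a whole number.",
          class = "stopphys_invalid_design")
  }
  if (is.unsorted(stim_times_ms, strictly = TRUE)) {
    abort("`stim_times_ms` must be sorted strictly ascending.",
          class = "stopphys_invalid_design")
  }
  if (ssd_step_ms <= 0) {
    abort("`ssd_step_ms` must be positive.", class = "stopphys_invalid_design")
  }
  structure(
    list(
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      stop_fraction = stop_fraction,
      modality_order = modality_order,
      stim_times_ms = as.numeric(stim_times_ms),
      baseline_probe_times_ms = as.numeric(baseline_probe_times_ms),
      paired_pulse = isTRUE(paired_pulse),
      ssd_init_ms = as.numeric(ssd_init_ms),
      ssd_step_ms = as.numeric(ssd_step_ms),
      response_window_ms = as.numeric(response_window_ms),
      seed = as.integer(seed)
    ),
    class = "design_config"
  )
}

#' Canonical study designs
#'
#' `exp1_design()` is the single-pulse design (12 x 90 trials, probes at
#' 150/200/250 ms). `exp2_design()` is the paired-pulse SICI design: the
#' 200 ms probe is dropped and single-/paired-pulse blocks alternate in pairs.
#'
#' @param seed RNG seed.
#' @param ... Overrides passed to [design_config()].
#' @return A `design_config`.
#' @export
exp1_design <- function(seed = 1L, ...) {
  design_config(seed = seed, ...)
}

#' @rdname exp1_design
#' @export
exp2_design <- function(seed = 1L, ...) {
  design_config(stim_times_ms = c(150, 250), paired_pulse = TRUE,
                seed = seed, ...)
}

#' Horse-race model parameters
#'
#' Go finishing times are ex-Gaussian (Normal(`go_mu`, `go_sigma`) plus
#' Exponential(`go_tau`)); the stop process finishes `ssrt_true` ms after the
#' stop signal whenever it triggers (probability `1 - trigger_failure_p`).
#' The defaults for [race_params_manual()] and [race_params_vocal()] give the
#' vocal task faster responses, matching the direction of the behavioral
#' findings the simulator emulates, with a common 220 ms stopping latency.
#'
#' @param go_mu,go_sigma,go_tau Ex-Gaussian parameters of the go process (ms).
#' @param ssrt_true True stop-signal reaction time (ms).
#' @param trigger_failure_p Probability the stop process fails to launch.
#' @return A `race_params` list.
#' @export
race_params <- function(go_mu, go_sigma, go_tau, ssrt_true,
                        trigger_failure_p = 0) {
  stopifnot(go_sigma > 0, go_tau >= 0, ssrt_true > 0,
            trigger_failure_p >= 0, trigger_failure_p < 1)
  structure(
    list(go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
         ssrt_true = ssrt_true, trigger_failure_p = trigger_failure_p),
    class = "race_params"
  )
}

#' @rdname race_params
#' @export
race_params_manual <- function() race_params(480, 60, 80, 220)

#' @rdname race_params
#' @export
race_params_vocal <- function() race_params(430, 55, 70, 220)

#' Pause-then-cancel generative model parameters
#'
#' The generative corticospinal-excitability (CSE) model used for synthetic
#' MEP amplitudes. Stopping engages two Gaussian-bell suppression processes
#' time-locked to the stop signal: a broad, early-peaking Pause affecting any
#' probed effector, and a later, narrower Cancel restricted to the responding
#' effector. Go-related facilitation rises linearly from go-signal onset in
#' the responding effector only. The default Pause bell is broad (width
#' 150 ms) so that non-selective suppression stays near-flat across the
#' 150-250 ms probe window while selective suppression grows late, the
#' qualitative pattern the model is meant to emulate.
#'
#' @param pause_amp,pause_peak_ms,pause_width_ms Pause bell: amplitude
#'   (unitless suppression of the scaling factor), peak latency after the stop
#'   signal (ms), Gaussian SD (ms).
#' @param cancel_amp,cancel_peak_ms,cancel_width_ms Cancel bell, same units.
#'   `pause_peak_ms < cancel_peak_ms` is asserted (the model's core timing
#'   assumption).
#' @param go_facilitation_slope Linear CSE gain per ms after go onset
#'   (responding effector only).
#' @param floor Lower bound on the scaling factor (excitability never reaches
#'   exactly zero).
#' @return A `pause_cancel_params` list.
#' @export
pause_cancel_params <- function(pause_amp = 0.35, pause_peak_ms = 150,
                                pause_width_ms = 150,
                                cancel_amp = 0.45, cancel_peak_ms = 250,
                                cancel_width_ms = 60,
                                go_facilitation_slope = 5e-4,
                                floor = 0.05) {
  stopifnot(pause_amp >= 0, cancel_amp >= 0,
            pause_width_ms > 0, cancel_width_ms > 0,
            floor > 0)
  if (!(pause_peak_ms < cancel_peak_ms)) {
    abort("Model assumption violated: `pause_peak_ms` must precede `cancel_peak_ms`.")
  }
  structure(
    list(pause_amp = pause_amp, pause_peak_ms = pause_peak_ms,
         pause_width_ms = pause_width_ms,
         cancel_amp = cancel_amp, cancel_peak_ms = cancel_peak_ms,
         cancel_width_ms = cancel_width_ms,
         go_facilitation_slope = go_facilitation_slope, floor = floor),
    class = "pause_cancel_params"
  )
}

#' EMG trace synthesis parameters
#'
#' Controls the synthetic single-channel EMG recordings: sampling rate,
#' recording noise, tonic (voluntary contraction) background for
#' silent-period-bearing trials, MEP size and latency, stimulus-artifact size,
#' and the cortical-silent-period generative terms. The default tonic level
#' (0.04 mV RMS) deliberately sits below the 0.05 mV pre-pulse-RMS rejection
#' ceiling so contracted trials still yield valid MEPs.
#'
#' @param sampling_rate_hz Samples per second; at least 2000 so the
#'   10-50 ms MEP window is well resolved.
#' @param noise_rms_mv Gaussian recording-noise RMS (mV).
#' @param tonic_rms_mv Background contraction RMS on tonic trials (mV).
#' @param mep_base_amp_mv Peak-to-peak MEP amplitude at scaling 1 (mV).
#' @param mep_amp_cv Trial-to-trial coefficient of variation of the MEP
#'   amplitude (multiplicative lognormal jitter with mean 1); 0 disables it.
#' @param mep_latency_ms MEP onset latency after the pulse (ms); the biphasic
#'   waveform lasts `mep_duration_ms`.
#' @param mep_duration_ms Duration of the biphasic MEP (ms).
#' @param artifact_amp_mv Stimulus artifact amplitude (mV).
#' @param csp_base_ms Baseline silent-period duration, pulse to resumption (ms).
#' @param csp_gain_ms Stop-related CSP prolongation at the Cancel peak (ms);
#'   scaled by the unit Cancel bell at the probe's post-stop latency.
#' @param csp_sd_ms Trial-to-trial SD of the true CSP duration (ms).
#' @param burst_rms_mv Voluntary response-burst RMS on responded manual
#'   trials (mV).
#' @param sici_base_frac,sici_stop_delta Conditioned-pulse MEP attenuation:
#'   paired-pulse MEPs are scaled by `1 - frac`, with
#'   `frac = sici_base_frac + sici_stop_delta` on stop trials (a global,
#'   time-invariant stop-related SICI increase). Synthetic values, not
#'   literature estimates.
#' @param trace_duration_ms Length of each trial's recording (ms).
#' @return A `trace_synth_params` list.
#' @export
trace_synth_params <- function(sampling_rate_hz = 5000,
                               noise_rms_mv = 0.005,
                               tonic_rms_mv = 0.04,
                               mep_base_amp_mv = 1.0,
                               mep_amp_cv = 0.2,
                               mep_latency_ms = 22,
                               mep_duration_ms = 15,
                               artifact_amp_mv = 2.0,
                               csp_base_ms = 120,
                               csp_gain_ms = 60,
                               csp_sd_ms = 8,
                               burst_rms_mv = 0.15,
                               sici_base_frac = 0.35,
                               sici_stop_delta = 0.10,
                               trace_duration_ms = 1200) {
  stopifnot(sampling_rate_hz >= 2000,
            noise_rms_mv >= 0, tonic_rms_mv >= 0, mep_base_amp_mv >= 0,
            artifact_amp_mv >= 0, csp_base_ms > 0, mep_duration_ms > 0)
  structure(
    list(sampling_rate_hz = sampling_rate_hz, noise_rms_mv = noise_rms_mv,
         tonic_rms_mv = tonic_rms_mv, mep_base_amp_mv = mep_base_amp_mv,
         mep_amp_cv = mep_amp_cv,
         mep_latency_ms = mep_latency_ms, mep_duration_ms = mep_duration_ms,
         artifact_amp_mv = artifact_amp_mv, csp_base_ms = csp_base_ms,
         csp_gain_ms = csp_gain_ms, csp_sd_ms = csp_sd_ms,
         burst_rms_mv = burst_rms_mv, sici_base_frac = sici_base_frac,
         sici_stop_delta = sici_stop_delta,
         trace_duration_ms = trace_duration_ms),
    class = "trace_synth_params"
  )
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat(sprintf("  %d blocks x %d trials (%s), stop fraction %.3f\n",
              x$n_blocks, x$trials_per_block, x$modality_order,
              x$stop_fraction))
  cat(sprintf("  stim times: %s ms | baseline probes: %s ms | %s-pulse\n",
              paste(x$stim_times_ms, collapse = "/"),
              paste(x$baseline_probe_times_ms, collapse = "/"),
              if (x$paired_pulse) "single+paired" else "single"))
  cat(sprintf("  SSD init %g ms, step %g ms, window %g ms, seed %d\n",
              x$ssd_init_ms, x$ssd_step_ms, x$response_window_ms, x$seed))
  invisible(x)
}
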