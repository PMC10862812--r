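# Default stopphys run configuration.
# Groups mirror the constructors: design_config(), race_params(),
# pause_cancel_params(), trace_synth_params(), plus the analysis thresholds.
design:
  n_blocks: 12                  # 12 alternating manual/vocal blocks
  trials_per_block: 90          # 1080 trials total
  stop_fraction: 0.33333333333333331
  modality_order: manual-first
  stim_times_ms: [150.0, 200.0, 250.0]   # task-pulse probe latencies
  baseline_probe_times_ms: [500.0, 700.0, 900.0]  # inter-trial probes
  paired_pulse: no              # yes = alternating single/paired (SICI) blocks
  ssd_init_ms: 200.0            # staircase start
  ssd_step_ms: 50.0             # 1-up/1-down step
  response_window_ms: 1000.0    # response deadline
  seed: 1
race_manual:
  go_mu: 480.0                  # ex-Gaussian go process, manual task (ms)
  go_sigma: 60.0
  go_tau: 80.0
  ssrt_true: 220.0              # generative stopping latency (ms)
  trigger_failure_p: 0.0
race_vocal:
  go_mu: 430.0                  # vocal responses faster than manual
  go_sigma: 55.0
  go_tau: 70.0
  ssrt_true: 220.0
  trigger_failure_p: 0.0
model:
  pause_amp: 0.35               # broad early suppression, any effector
  pause_peak_ms: 150.0
  pause_width_ms: 150.0
  cancel_amp: 0.45              # late suppression, responding effector only
  cancel_peak_ms: 250.0
  cancel_width_ms: 60.0
  go_facilitation_slope: 0.0005 # CSE gain per ms after go onset
  floor: 0.05                   # scaling never reaches zero
synth:
  sampling_rate_hz: 5000.0
  noise_rms_mv: 0.005
  tonic_rms_mv: 0.04            # below the 0.05 mV pre-pulse rejection ceiling
  mep_base_amp_mv: 1.0
  mep_amp_cv: 0.2               # trial-to-trial MEP variability
  mep_latency_ms: 22.0
  mep_duration_ms: 15.0
  artifact_amp_mv: 2.0
  csp_base_ms: 120.0            # silent period, pulse to resumption
  csp_gain_ms: 60.0             # stop-related prolongation at the Cancel peak
  csp_sd_ms: 8.0
  burst_rms_mv: 0.15
  sici_base_frac: 0.35          # conditioned-pulse MEP attenuation
  sici_stop_delta: 0.1          # extra attenuation on stop trials
  trace_duration_ms: 1200.0
analysis:
  mode: exp1
  amp_min_mv: 0.05              # MEPs below this are rejected
  rms_max_mv: 0.05              # pre-pulse RMS above this is rejected
  mep_window_ms: [10.0, 50.0]   # peak-to-peak window after the pulse
  prepulse_span_ms: 80.0        # RMS span before the pulse
  tail_fraction: 0.05           # extreme-MEP trimming per tail (exp1 only)
  trim: yes
  min_meps: 15                  # per-cell inclusion (10 in exp2 mode)
  min_failed_stop_meps: 10      # failed-stop CSE analyses
  min_failed_stop_csps: 5       # failed-stop silent-period analyses
  d_threshold: 0.2              # smallest effect counting as "shown"
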