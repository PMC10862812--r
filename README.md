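# stopphys

Simulation and analysis of motor-system physiology in stop-signal tasks.

## The problem

Stopping an initiated action can be described by a single inhibitory "stop"
process racing the go process, or by two processes: a fast, *global* Pause
that transiently suppresses the whole motor system after any salient event,
and a slower, effector-*selective* Cancel directed at the action being
stopped. TMS/EMG experiments adjudicate between these accounts by probing
one muscle's corticospinal excitability (CSE) at a few latencies after the
stop signal, both when that muscle is the responding effector (manual task)
and when it is task-unrelated (vocal task), alongside paired-pulse SICI and
the cortical silent period (CSP).

`stopphys` is for researchers and methodologists working with such data. It
simulates the whole study at desk scale — choice stop-signal behavior under
the independent race model with adaptive SSD staircase tracking, plus
single-trial EMG traces whose MEP amplitudes follow a parameterized
pause-then-cancel model — and provides the complete measurement pipeline to
recover behavior and physiology from the recordings. Every synthetic trial
stores its injected ground truth, so each analysis stage is testable against
a recoverable answer.

## The model in brief

Go finishing times are ex-Gaussian, `N(mu, sigma^2) + Exp(tau)`; a stop
trial is inhibited when the stop process, finishing at `SSD + SSRT`, beats
the go process. SSDs track 1-up/1-down in 50 ms steps from 200 ms, driving
p(inhibit) to ~0.5. SSRT is recovered by the integration method: with go
RTs sorted (omissions replaced by the max go RT), the RT at rank
`ceiling(p(respond|signal) * N)` minus the mean SSD.

The expected MEP scaling for a probe at time `t` after go onset is

    s(t) = 1 + beta * t * [responding]
             - Pause(t - SSD) * [stop trial]
             - Cancel(t - SSD) * [stop trial & responding]

with Gaussian-bell Pause (broad, peaking 150 ms post-stop) and Cancel
(narrow, peaking 250 ms, responding effector only). Measurement follows the
standard conventions: peak-to-peak amplitude 10–50 ms post pulse; rejection
for amplitudes < 0.05 mV, pre-pulse RMS > 0.05 mV, or responses at/before
the pulse; optional 5% tail trimming; CSE normalized to active baseline;
`SICI% = (TS - CS)/TS * 100`; CSP from pulse to the refined EMG-resumption
point. Per participant, Cohen's d (go vs successful stop) per task and probe
time feeds a six-way classification of suppression timing
(global-then-selective, selective-then-global, same-time, global-only,
selective-only, neither).

## Worked example

One participant, full single-pulse design (12 blocks × 90 trials):

```r
library(stopphys)

cfg    <- exp1_design(seed = 42)
events <- simulate_participant(cfg)
summarize_behavior(events)
#>   modality n_trials n_go n_stop mean_go_rt mean_failed_stop_rt p_inhibit
#> 1   manual      540  360    180      569.6               492.7    0.5167
#> 2    vocal      540  360    180      499.5               441.8    0.5000
#>   mean_ssd omission_rate  ssrt
#> 1    316.1             0 239.5
#> 2    276.4             0 210.2
```

Failed-stop RTs are faster than go RTs, p(inhibit) sits at one half, and the
integration-method SSRTs bracket the generative 220 ms. Physiology:

```r
traces <- synthesize_traces(events, seed = 42)
meas   <- measure_meps(traces) |> apply_rejection(events)
csp    <- measure_csps(traces, events, meas)
summarize_conditions(meas, events, mode = "exp1", csp = csp)
#>    modality trial_type   stim_time_ms n_meps normalized_cse mean_csp_ms
#>  1 manual   baseline               NA    162          1           122.
#>  2 manual   go                    150     54          1.04        121.
#>  3 manual   go                    200     54          1.15        122.
#>  4 manual   go                    250     54          1.12        121.
#>  5 manual   stop-success          150     29          0.801       137.
#>  6 manual   stop-success          200     35          0.656       163.
#>  7 manual   stop-success          250     23          0.589       181.
#>  8 vocal    baseline               NA    162          1            NA
#>  9 vocal    go                    150     54          1.02         NA
#> 10 vocal    go                    200     54          1.03         NA
#> 11 vocal    go                    250     54          0.956        NA
#> 12 vocal    stop-success          150     25          0.641        NA
#> 13 vocal    stop-success          200     23          0.645        NA
#> 14 vocal    stop-success          250     36          0.731        NA
```

Stop-related CSE suppression deepens over time in the responding effector
(manual stop cells: 0.80 → 0.66 → 0.59) but not in the task-unrelated one
(vocal: 0.64 → 0.65 → 0.73), and silent periods lengthen late on stop trials
(137 → 163 → 181 ms vs ~121 ms on go) — the pause-then-cancel signature the
generator encodes. The participant-level profile makes the same point:

```r
profiles <- compute_effect_profiles(meas, events)
profiles
#>   participant stim_time_ms nonselective_d selective_d
#> 1 s01                  150           1.96      -0.521
#> 2 s01                  200           2.14       0.955
#> 3 s01                  250           1.50       0.799
classify_profiles(profiles)
#>   participant category
#> 1 s01         global-then-selective
```

`run_pipeline(out_dir, config, n_participants, seed)` (or the thin CLI at
`inst/cli/stopphys.R`) runs simulate → extract → classify against TSV/JSON
files on disk, with a YAML config (`inst/extdata/default-config.yaml`
documents every threshold) and a JSON run manifest; reruns with the same
config and seed are byte-identical.

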