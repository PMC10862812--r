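---
title: "Simulating and measuring stop-signal TMS/EMG physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and measuring stop-signal TMS/EMG physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopphys)
library(dplyr)
```

## What the package models

Action-stopping experiments that combine a stop-signal task (SST) with
transcranial magnetic stimulation (TMS) probe the excitability of a single
muscle — here the right flexor digitorum superficialis (FDS) — while a
participant either responds with the hand (manual task, FDS task-related) or
with the voice (vocal task, FDS task-unrelated). Motor-evoked potentials
(MEPs) elicited at a few latencies after the go or stop signal index
corticospinal excitability (CSE); paired-pulse protocols add short-interval
intracortical inhibition (SICI), and the interruption of tonic EMG after the
MEP gives the cortical silent period (CSP).

`stopphys` provides two halves that meet in the middle:

1. a **simulator** that generates the full study at desk scale — trial
   sequences with adaptive stop-signal-delay (SSD) tracking, race-model
   behavior, and per-trial EMG traces and vocal envelopes whose ground truth
   follows a parameterized *pause-then-cancel* excitability model — and
2. a **measurement pipeline** that recovers behavior (RTs, p(inhibit), SSRT)
   and physiology (MEP amplitude, normalized CSE, SICI, CSP duration) from
   those recordings, ending in a per-participant classification of
   suppression timing.

Because every synthetic trial stores the values that were injected into it,
each stage of the pipeline can be validated against a recoverable truth.

## The behavioral generative model

Go finishing times are ex-Gaussian:
$T_{go} \sim \mathcal{N}(\mu, \sigma^2) + \mathrm{Exp}(\tau)$, with
per-modality parameters (defaults: manual $\mu=480, \sigma=60, \tau=80$ ms;
vocal $\mu=430, \sigma=55, \tau=70$ ms, so vocal responses are faster, the
direction such dual-task data show). The ex-Gaussian family is the standard
descriptive model for RT distributions; the generative family is not fixed
by the measurement procedure, so this is a package design choice.

On a stop trial the stop process finishes at $SSD + SSRT$ whenever it
triggers (probability $1 -$ `trigger_failure_p`, default 1). A response is
emitted only if the go process wins *and* finishes inside the 1000 ms
response window; a stop trial without an emitted response is scored as a
successful stop, exactly as an observer would score it. SSRT is constant per
participant (default 220 ms in both tasks, matching the empirical finding
that SSRT does not differ between them).

SSDs follow the standard 1-up/1-down staircase — success makes the next stop
harder (+50 ms), failure easier (−50 ms), floor 0 — initialized at 200 ms
and tracked separately per (modality × response) cell. The direction of the
update rule is a convention the tracking outcome pins down: it is the rule
that drives p(inhibit) toward 0.5, which is what the empirical p(inhibit)
values (≈ 0.49–0.52) reflect. Simulated cohorts land at ≈ 0.51: the small
positive offset comes from the staircase starting below its convergence
point, so the early stop trials are disproportionately easy.

### Trial sequences

Within every block of 90 trials, 30 are stop trials, all with a task TMS
pulse; 30 go trials carry task pulses and 30 are baseline-probe trials
(TMS delivered in the inter-trial interval before a go trial whose
predecessor is also a go trial). Probe latencies (150/200/250 ms task,
500/700/900 ms baseline) are balanced exactly within block and trial type;
orderings are rejection-sampled until enough consecutive-go positions exist.
Designs whose counts cannot balance exactly raise an invalid-design error
rather than approximating. In paired-pulse mode (the SICI design) the pulse
type alternates in pairs of blocks, so each mode covers both modalities, and
the 200 ms probe is dropped.

## The pause-then-cancel CSE model

The expected MEP scaling (relative to active baseline) for a probe at time
$t$ after go onset, on a trial with stop-signal onset at $SSD$, is

$$ s(t) = 1 + \beta\, t \cdot [\text{responding}]
        - P(t - SSD) \cdot [\text{stop}]
        - C(t - SSD) \cdot [\text{stop} \wedge \text{responding}], $$

floored at 0.05, where $P$ and $C$ are Gaussian bells
$A \exp\{-(x - p)^2 / 2w^2\}$. Defaults: Pause $A=0.35$, peak 150 ms,
width 150 ms; Cancel $A=0.45$, peak 250 ms, width 60 ms; facilitation slope
$\beta = 5\times10^{-4}$/ms. Two properties drove the defaults:

* the Pause bell is **broad**, so non-selective suppression (vocal task,
  hand probe) is near-flat across the 150–250 ms probe window — the pattern
  group data show, where non-selective suppression is "less transient than
  expected" — while still peaking before the Cancel process, preserving the
  model's core timing assumption (asserted in the constructor);
* the Cancel bell is late and narrow, so responding-effector suppression at
  matched post-stop latencies is non-decreasing over 150→200→250 ms.

Because stop-trial probes are time-locked to the stop signal (pulse at
$SSD + $ stim time) while go probes are locked to the go signal, go-related
facilitation contributes $\beta \cdot SSD$ more on stop than on matched go
trials; a modest $\beta$ keeps the selective (manual − vocal) effect-size
profile positive at the late timepoint and increasing with time.

## Trace synthesis

Each TMS trial renders a 5 kHz (configurable, ≥ 2 kHz) single-channel EMG
trace in mV: Gaussian recording noise (0.005 mV RMS), a decaying stimulus
artifact at the pulse, and a biphasic MEP (two half-sine lobes, 22 ms
latency, 15 ms duration) whose *sampled* peak-to-peak amplitude equals the
injected value exactly — the discrete waveform is renormalized so round
trips are exact in the noiseless limit. Injected amplitudes are
`mep_base_amp_mv × s(t)`, times a mean-1 lognormal trial-to-trial jitter
(CV 0.2, the dominant source of within-cell variance, as in real MEP data),
times $(1 - \mathrm{SICI})$ on paired-pulse trials
(SICI fraction 0.35, +0.10 on stop trials: a global, time-invariant
stop-related SICI increase, qualitatively matching the paired-pulse
findings; the numbers are synthetic, not literature estimates).

Manual-modality single-pulse trials additionally carry tonic background EMG
at 0.04 mV RMS that falls silent from MEP offset until the trial's true CSP
duration (base 120 ms from the pulse, prolonged on stop trials by up to
60 ms scaled by the unit Cancel bell, ±8 ms trial noise) and then resumes.
The tonic level sits deliberately *below* the 0.05 mV pre-pulse-RMS
rejection ceiling: the preprocessing rules both reject trials with
pre-pulse EMG above 0.05 mV and score CSPs on task trials, which is only
consistent if contracted trials stay under that ceiling. Responded manual
trials add a voluntary burst at the RT; baseline probes are separate
inter-trial recordings with the pulse at a fixed offset and no response
activity. Vocal envelopes are non-negative with a bounded noise floor
(uniform, so a threshold above the bound can never false-trigger) and a
supra-threshold burst whose first sample sits at the true RT.

## Measurement conventions

* **MEP amplitude**: max − min over the closed 10–50 ms post-pulse window;
  times convert to samples by rounding. The pulse is localized as the
  maximum absolute deflection within ±5 ms of schedule (a stand-in for
  per-trial visual verification), flagged when implausibly small.
* **Pre-pulse RMS**: raw-trace RMS over the 80 ms before the pulse. On
  paired-pulse trials the window ends 4 ms early so the conditioning-pulse
  artifact is not counted as muscle activity.
* **Rejection** (first matching reason recorded): amplitude < 0.05 mV;
  pre-pulse RMS > 0.05 mV; response at or before the pulse on task pulses.
  The RT rule discards trials whose MEP window is contaminated by the
  voluntary response — which is why failed stops (the fast tail of the go
  distribution) are rejected disproportionately. Baseline probes, delivered
  before the trial starts, are exempt.
* **Trimming**: the single-pulse study mode additionally drops the
  ⌊5%⌋ smallest and largest accepted amplitudes per condition cell
  (after rejection, which is the only order that makes the two rules
  commute sensibly); the paired-pulse mode does not trim.
* **Inclusion**: participants need ≥ 15 usable MEPs per go and
  successful-stop cell (single-pulse mode), 10 (paired-pulse mode), 5 for
  failed-stop CSP analyses; all thresholds are configurable.
* **CSE**: per-cell mean amplitude divided by the same-effector single-pulse
  active-baseline mean. **SICI** = (TS − CS)/TS × 100 from the cell's
  unconditioned vs conditioned mean amplitudes, baselines included.
* **CSP**: scored only on manual-task single-pulse trials with a valid MEP.
  The analyst's judgment is automated: a 5-ms centred moving-RMS envelope
  must fall below 25% of the pre-pulse tonic RMS for ≥ 20 ms (else no CSP),
  and the candidate resumption is the first ≥ 5 ms stretch back above 50%
  of tonic, sharpened to the first supra-threshold raw deflection near the
  crossing, then refined to the maximum absolute deflection within ±2 ms —
  the same refinement an analyst's mark receives. Duration is measured from
  the pulse (absolute convention; the pulse time is unambiguous, MEP offset
  is noise-sensitive). A 25-ms envelope was considered and rejected: it
  smears the silence-to-activity transition and biases the mark by ~6 ms,
  which a ±2 ms refinement cannot undo. Traces whose tonic reference does
  not exceed the noise floor are flagged not-contracting and never scored —
  the hand during the vocal task.

## Effect-size profiles and classification

Per participant, modality and stim time, Cohen's d contrasts go vs
successful-stop amplitudes (pooled-SD two-sample d: the two trial sets are
independent samples within a participant; d is scale-free, so baseline
normalization is immaterial). The non-selective profile is the vocal-task
(hand-probe) d; the selective profile subtracts, at each time, the
non-selective d from the manual-task d.

A suppression type is *shown* if any timepoint's d exceeds 0.2. Neither
shown → `neither`; one → `global-only`/`selective-only`. When both are
shown, each type's characteristic timepoint is the one with the greatest
increase relative to previous timepoints, where the first timepoint's
increase is its d (i.e. relative to an implicit 0), increases ≤ 0.2
disqualify a timepoint (if none qualifies, the greatest increase wins
regardless — a shown type always gets a timepoint), and ties resolve to the
earliest timepoint. "Previous timepoints" is read as the running maximum of
0 and all earlier d values; a strictly pairwise reading
(`increase = "pairwise"`) is available, and the two genuinely differ for
profiles that dip and recover. Earlier global timepoint →
`global-then-selective`; later → `selective-then-global`; equal →
`same-time`. Two-timepoint designs use the same rules verbatim.

At realistic cell sizes the sampling SD of d is ≈ 0.2–0.4, so a truly-null
process still crosses the 0.2 threshold in a sizeable minority of
participants; cohort-level checks therefore target the *modal* category,
not unanimity.

The generative amplitudes are also directly recoverable:
`fit_suppression_amplitudes()` exploits that, with the bell shapes and
facilitation slope fixed, the cell-mean model is linear in the Pause and
Cancel amplitudes, and fits both by least squares to the 12 task cells
(`tidy()`/`glance()`/`autoplot()` methods included).

## What the simulator does and does not emulate

The generator reproduces the study's *structure*: balanced scheduling,
staircase dynamics, race-consistent behavior (failed-stop RT < go RT),
MEP-amplitude scaling with recoverable pause/cancel time courses,
rejection-prone failed stops, silent periods, SICI attenuation, and vocal
onsets. It does not emulate: electrode artifacts or drift, spectral EMG
content (noise is white; real EMG is band-limited), MEP latency or shape
variability, partial subthreshold EMG bursts on successful stops, acoustic
voice content, or between-participant parameter heterogeneity (cohorts
share one parameter set unless varied by the caller). Passing tests
therefore certify the pipeline's correctness on data with known structure,
not the physiological realism of any particular parameter value.

## Numerical choices and problem sizes

All times are ms; amplitudes mV; conversions round to the nearest sample.
Sequence generation rejection-samples orderings (deterministically under the
config seed) and errors after 1000 attempts. Seeds: every stochastic
function takes an explicit seed or inherits the caller's RNG state; cohort
seeds derive from one master seed, and equal config + seed reproduces output
files byte-identically. The test suite exercises full-scale designs where
the property demands it (24- and 14-participant cohorts for tracking, 100
participants for SSRT recovery, 500 trials for CSP recovery, 12-participant
cohorts at 2 kHz for the end-to-end classification checks) and 2–4-block
designs elsewhere; these sizes are the package's chosen validation scale.

## Known limitations

* The automated CSP presence criterion is an explicit stand-in for an
  analyst's visual judgment, not a reconstruction of it; its three constants
  are documented defaults, not empirical estimates.
* The integration-method SSRT uses ceiling rank without interpolation and
  replaces go omissions with the maximum observed go RT (the consensus
  treatment); both are configurable conventions.
* Choice errors are not modeled (responded go trials are all "correct"),
  mirroring analyses in which errors are rare and not analyzed.
* Whether 5% trimming should floor, round, or ceil is unspecified in the
  procedure it mirrors; `floor` is used and documented.
* The SSD trackers are shared across single- and paired-pulse blocks
  (per modality × response only); tracking per pulse mode would halve each
  tracker's trial count without changing its equilibrium.
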