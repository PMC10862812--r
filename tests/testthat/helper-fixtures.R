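# Small designs and quiet synthesis settings shared across tests.

tiny_design <- function(seed = 1L, ...) {
  design_config(n_blocks = 2, trials_per_block = 18, seed = seed, ...)
}

# Noise-free synthesis: exact round trips.
noiseless_synth <- function(sampling_rate_hz = 2000) {
  trace_synth_params(sampling_rate_hz = sampling_rate_hz,
                     noise_rms_mv = 0, tonic_rms_mv = 0, burst_rms_mv = 0,
                     mep_amp_cv = 0, csp_sd_ms = 0)
}

# Simulate one participant with traces and rejection-annotated measurements.
sim_session <- function(config = tiny_design(),
                        model = pause_cancel_params(),
                        synth = trace_synth_params(sampling_rate_hz = 2000),
                        seed = 1L) {
  events <- simulate_participant(config)
  traces <- synthesize_traces(events, model, synth, seed = seed)
  measurements <- apply_rejection(measure_meps(traces), events)
  list(events = events, traces = traces, measurements = measurements)
}

# Closed-form ex-Gaussian CDF (normal + exponential convolution), used as the
# independent oracle for race-outcome probabilities.
pexgauss <- function(q, mu, sigma, tau) {
  z <- (q - mu) / sigma
  pnorm(z) - exp(-(q - mu) / tau + sigma^2 / (2 * tau^2)) *
    pnorm(z - sigma / tau)
}

# Independent, literal re-enactment of the classification rules, written as
# plain loops so the package implementation is checked against a second,
# structurally different reading of the same procedure.
brute_force_classify <- function(g, s, thr = 0.2) {
  shown <- function(v) {
    for (x in v) if (x > thr) return(TRUE)
    FALSE
  }
  winner <- function(v) {
    inc <- numeric(length(v))
    for (t in seq_along(v)) {
      prev <- 0
      if (t > 1) for (u in 1:(t - 1)) if (v[u] > prev) prev <- v[u]
      inc[t] <- v[t] - prev
    }
    qual <- which(inc > thr)
    if (length(qual) == 0) qual <- seq_along(inc)
    best <- qual[1]
    for (t in qual) if (inc[t] > inc[best]) best <- t
    best
  }
  sg <- shown(g); ss <- shown(s)
  if (!sg && !ss) return("neither")
  if (sg && !ss) return("global-only")
  if (!sg && ss) return("selective-only")
  tg <- winner(g); ts <- winner(s)
  if (tg < ts) "global-then-selective"
  else if (tg > ts) "selective-then-global"
  else "same-time"
}

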