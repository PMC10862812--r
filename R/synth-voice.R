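#' Synthesize vocal-response amplitude envelopes
#'
#' For every vocal-modality trial, renders a non-negative amplitude envelope:
#' a bounded noise floor (uniform on `[0, noise_amp]`, so it can never cross a
#' threshold above `noise_amp`) plus, when the trial has a response, a
#' supra-threshold burst whose first sample sits exactly at the trial's RT.
#' Successful stops and omissions contain no burst.
#'
#' @param events Simulated events tibble.
#' @param sampling_rate_hz Envelope sampling rate (Hz).
#' @param noise_amp Noise-floor ceiling (arbitrary amplitude units).
#' @param burst_amp Peak burst amplitude.
#' @param duration_ms Envelope length (ms).
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A `voice_envelopes` object: list with `signal` (trials x samples
#'   matrix), `meta` (tibble `trial`, `true_rt_ms`), `sampling_rate_hz`.
#' @export
synth_voice_envelope <- function(events,
                                 sampling_rate_hz = 1000,
                                 noise_amp = 0.01,
                                 burst_amp = 1,
                                 duration_ms = 1500,
                                 seed = NULL) {
  run <- function() {
    vocal <- events[events$modality == "vocal", , drop = FALSE]
    if (nrow(vocal) == 0) abort("No vocal trials in `events`.")
    sr <- sampling_rate_hz
    n <- ms_to_samples(duration_ms, sr) + 1L
    ramp_k <- ms_to_samples(20, sr)
    burst_k <- ms_to_samples(300, sr)

    signal <- matrix(runif(nrow(vocal) * n, 0, noise_amp), nrow = nrow(vocal))
    for (i in seq_len(nrow(vocal))) {
      rt <- vocal$rt_ms[i]
      if (!is.na(rt)) {
        i0 <- ms_to_samples(rt, sr) + 1L
        if (i0 <= n) {
          idx <- i0:min(i0 + burst_k, n)
          shape <- c(seq(0.2, 1, length.out = ramp_k),
                     rep(1, max(0, length(idx) - ramp_k)))[seq_along(idx)]
          signal[i, idx] <- burst_amp * shape
        }
      }
    }
    structure(
      list(signal = signal,
           meta = tibble(trial = vocal$trial, true_rt_ms = vocal$rt_ms),
           sampling_rate_hz = sr),
      class = "voice_envelopes"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.voice_envelopes <- function(x, ...) {
  cat(sprintf("<voice_envelopes> %d trials x %d samples @ %g Hz\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate_hz))
  invisible(x)
}
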