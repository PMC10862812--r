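events_columns <- c("trial", "block", "modality", "trial_type", "ssd_ms",
                    "rt_ms", "outcome", "tms_role", "tms_time_ms",
                    "pulse_type")

#' Read and write events tables
#'
#' The on-disk events table is a TSV with exactly one row per trial and the
#' columns `trial, block, modality, trial_type, ssd_ms, rt_ms, outcome,
#' tms_role, tms_time_ms, pulse_type`; missing values are written as `"NA"`.
#' [read_events()] re-derives the `stim_time_ms` helper column (probe latency
#' relative to its time-locking signal) from the stored times.
#'
#' @param events Events tibble.
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   the events tibble.
#' @export
write_events <- function(events, path) {
  events |>
    select(dplyr::all_of(events_columns)) |>
    readr::write_tsv(path, na = "NA")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                        col_types = readr::cols(
                          trial = "i", block = "i", modality = "c",
                          trial_type = "c", ssd_ms = "d", rt_ms = "d",
                          outcome = "c", tms_role = "c", tms_time_ms = "d",
                          pulse_type = "c"
                        ))
  ev |>
    mutate(stim_time_ms = case_when(
      tms_role != "task-pulse" ~ NA_real_,
      trial_type == "stop" ~ tms_time_ms - ssd_ms,
      TRUE ~ tms_time_ms
    ))
}

#' Read and write trace containers
#'
#' Traces are stored as a plain TSV numeric matrix (one row per TMS trial,
#' values in mV with 6 significant digits) next to a JSON sidecar
#' (`<prefix>.json`) holding the sampling rate, units, per-trial pulse sample
#' indices and times, and the ground-truth record when present.
#'
#' @param traces An `emg_traces` object.
#' @param prefix Path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return `write_traces()` returns `prefix` invisibly; `read_traces()`
#'   returns the `emg_traces` object.
#' @export
write_traces <- function(traces, prefix) {
  m <- signif(traces$signal, 6)
  utils::write.table(m, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  sidecar <- list(
    sampling_rate_hz = traces$sampling_rate_hz,
    units = traces$units,
    trial = traces$meta$trial,
    pulse_sample = traces$meta$pulse_sample,
    pulse_time_ms = traces$meta$pulse_time_ms,
    paired = traces$meta$paired,
    ground_truth = traces$truth
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(prefix)
}

#' @rdname write_traces
#' @export
read_traces <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"),
                                 simplifyVector = TRUE)
  signal <- as.matrix(readr::read_tsv(
    paste0(prefix, ".tsv"), col_names = FALSE, show_col_types = FALSE,
    col_types = readr::cols(.default = "d")))
  dimnames(signal) <- NULL
  structure(
    list(
      signal = signal,
      meta = tibble(trial = sidecar$trial,
                    pulse_sample = sidecar$pulse_sample,
                    pulse_time_ms = as.numeric(sidecar$pulse_time_ms),
                    paired = as.logical(sidecar$paired)),
      truth = if (!is.null(sidecar$ground_truth)) {
        as_tibble(sidecar$ground_truth)
      } else NULL,
      sampling_rate_hz = sidecar$sampling_rate_hz,
      units = sidecar$units
    ),
    class = "emg_traces"
  )
}

#' Read and write voice-envelope containers
#'
#' Same layout as [write_traces()]: a TSV matrix plus a JSON sidecar with the
#' sampling rate and the per-trial truth.
#'
#' @param envelopes A `voice_envelopes` object.
#' @param prefix Path prefix.
#' @return `write_voice()` returns `prefix` invisibly; `read_voice()` the
#'   object.
#' @export
write_voice <- function(envelopes, prefix) {
  utils::write.table(signif(envelopes$signal, 6), paste0(prefix, ".tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(sampling_rate_hz = envelopes$sampling_rate_hz,
         trial = envelopes$meta$trial,
         true_rt_ms = envelopes$meta$true_rt_ms),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(prefix)
}

#' @rdname write_voice
#' @export
read_voice <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"),
                                 simplifyVector = TRUE)
  signal <- as.matrix(readr::read_tsv(
    paste0(prefix, ".tsv"), col_names = FALSE, show_col_types = FALSE,
    col_types = readr::cols(.default = "d")))
  dimnames(signal) <- NULL
  structure(
    list(signal = signal,
         meta = tibble(trial = sidecar$trial,
                       true_rt_ms = as.numeric(sidecar$true_rt_ms)),
         sampling_rate_hz = sidecar$sampling_rate_hz),
    class = "voice_envelopes"
  )
}

#' Read and write the full run configuration
#'
#' The configuration file is YAML with one section per parameter group
#' (`design`, `race_manual`, `race_vocal`, `model`, `synth`, `analysis`),
#' covering every tunable the pipeline uses, including all preprocessing
#' thresholds. See `system.file("extdata", "default-config.yaml",
#' package = "stopphys")` for the annotated default.
#'
#' @param config A named list as returned by [default_run_config()].
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` the reconstructed list (with classed parameter
#'   objects).
#' @export
write_run_config <- function(config, path) {
  plain <- purrr::map(config, function(x) {
    if (is.list(x)) unclass(x) else x
  })
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  list(
    design = do.call(design_config, raw$design),
    race_manual = do.call(race_params, raw$race_manual),
    race_vocal = do.call(race_params, raw$race_vocal),
    model = do.call(pause_cancel_params, raw$model),
    synth = do.call(trace_synth_params, raw$synth),
    analysis = raw$analysis
  )
}

#' Default run configuration
#'
#' All parameter groups at their defaults, plus the analysis thresholds
#' (MEP rejection floor and pre-pulse RMS ceiling, MEP window, pre-pulse
#' span, trimming fraction, per-cell inclusion minima, effect-size
#' threshold).
#'
#' @param mode `"exp1"` or `"exp2"`.
#' @param seed Design seed.
#' @return Named list of parameter groups.
#' @export
default_run_config <- function(mode = c("exp1", "exp2"), seed = 1L) {
  mode <- match.arg(mode)
  list(
    design = if (mode == "exp1") exp1_design(seed) else exp2_design(seed),
    race_manual = race_params_manual(),
    race_vocal = race_params_vocal(),
    model = pause_cancel_params(),
    synth = trace_synth_params(),
    analysis = list(
      mode = mode,
      amp_min_mv = 0.05,
      rms_max_mv = 0.05,
      mep_window_ms = c(10, 50),
      prepulse_span_ms = 80,
      tail_fraction = 0.05,
      trim = mode == "exp1",
      min_meps = if (mode == "exp1") 15L else 10L,
      min_failed_stop_meps = 10L,
      min_failed_stop_csps = 5L,
      d_threshold = 0.2
    )
  )
}
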