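participant_dirs <- function(out_dir) {
  sort(list.dirs(out_dir, recursive = FALSE))
}

write_stage_manifest <- function(out_dir, stage, seed, files, config = NULL) {
  path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    list(package = "stopphys",
         version = as.character(utils::packageVersion("stopphys")),
         stages = list())
  }
  manifest$stages[[stage]] <- list(
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(files)
  )
  if (!is.null(config)) {
    manifest$config <- purrr::map(config, function(x) {
      if (is.list(x)) unclass(x) else x
    })
  }
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(manifest)
}

#' Simulate a study and write it to disk
#'
#' Generates `n_participants` sessions (trial sequences, race-model behavior,
#' EMG traces, voice envelopes) under `config` and writes one subdirectory
#' per participant (`sub-01/`, ...) containing `events.tsv`,
#' `traces.tsv/.json` and `voice.tsv/.json`, plus a `config.yaml` snapshot
#' and a JSON run manifest at the top level. Re-running with the same
#' configuration and seed reproduces the output files byte-identically
#' (the manifest's timestamp aside).
#'
#' @param out_dir Output directory (created if needed).
#' @param config A run configuration ([default_run_config()]).
#' @param n_participants Number of participants.
#' @param seed Master seed; per-participant seeds are derived from it.
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(out_dir, config = default_run_config(),
                         n_participants = 1L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  race <- list(manual = config$race_manual, vocal = config$race_vocal)
  seeds <- withr::with_seed(seed,
                            matrix(sample.int(.Machine$integer.max - 1L,
                                              3L * n_participants),
                                   ncol = 3L))
  files <- character()
  for (p in seq_len(n_participants)) {
    sub <- file.path(out_dir, sprintf("sub-%02d", p))
    dir.create(sub, showWarnings = FALSE)
    cfg <- config$design
    cfg$seed <- seeds[p, 1L]
    trials <- generate_trial_sequence(cfg)
    events <- simulate_behavior(trials, race, cfg, seed = seeds[p, 2L])
    traces <- synthesize_traces(events, config$model, config$synth,
                                seed = seeds[p, 3L])
    voice <- synth_voice_envelope(events, seed = seeds[p, 3L])
    write_events(events, file.path(sub, "events.tsv"))
    write_traces(traces, file.path(sub, "traces"))
    write_voice(voice, file.path(sub, "voice"))
    files <- c(files, file.path(sub, c("events.tsv", "traces.tsv",
                                       "traces.json", "voice.tsv",
                                       "voice.json")))
  }
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(write_stage_manifest(out_dir, "simulate", seed,
                                 c(files, file.path(out_dir, "config.yaml")),
                                 config))
}

#' Extract measurements and condition summaries from a simulated study
#'
#' For every participant directory written by [run_simulate()]: re-detects
#' vocal response onsets from the stored envelopes (replacing the vocal RTs,
#' as a voice pipeline would), measures MEPs and pre-pulse RMS from the
#' traces, applies the rejection rules, scores silent periods on eligible
#' trials, and writes `measurements.tsv`, `csp.tsv`, `summary.tsv` and
#' `behavior.tsv`. All floats are written with 6 significant digits.
#'
#' @param out_dir Study directory.
#' @param config Run configuration; `NULL` reads `config.yaml` from
#'   `out_dir`.
#' @return The manifest, invisibly.
#' @export
run_extract <- function(out_dir, config = NULL) {
  if (is.null(config)) {
    config <- read_run_config(file.path(out_dir, "config.yaml"))
  }
  an <- config$analysis
  files <- character()
  for (sub in participant_dirs(out_dir)) {
    events <- read_events(file.path(sub, "events.tsv"))
    traces <- read_traces(file.path(sub, "traces"))
    voice <- read_voice(file.path(sub, "voice"))

    onsets <- detect_voice_onsets(voice)
    idx <- match(onsets$trial, events$trial)
    events$rt_ms[idx] <- onsets$rt_ms

    meas <- measure_meps(traces, window_ms = an$mep_window_ms,
                         prepulse_span_ms = an$prepulse_span_ms) |>
      apply_rejection(events, an$amp_min_mv, an$rms_max_mv)
    csp <- measure_csps(traces, events, meas)
    summ <- summarize_conditions(meas, events, mode = an$mode, csp = csp,
                                 trim = an$trim,
                                 tail_fraction = an$tail_fraction)
    behav <- summarize_behavior(events)

    round6 <- function(d) mutate(d, dplyr::across(dplyr::where(is.double),
                                                  ~ signif(.x, 6)))
    readr::write_tsv(round6(meas), file.path(sub, "measurements.tsv"), na = "NA")
    readr::write_tsv(round6(csp), file.path(sub, "csp.tsv"), na = "NA")
    readr::write_tsv(round6(summ), file.path(sub, "summary.tsv"), na = "NA")
    readr::write_tsv(round6(behav), file.path(sub, "behavior.tsv"), na = "NA")
    files <- c(files, file.path(sub, c("measurements.tsv", "csp.tsv",
                                       "summary.tsv", "behavior.tsv")))
  }
  invisible(write_stage_manifest(out_dir, "extract", NA, files))
}

#' Classify participants from extracted measurements
#'
#' Applies the per-cell inclusion rule (at least `min_meps` usable MEPs in
#' every go and successful-stop cell), computes effect-size profiles for the
#' included participants, classifies each, and writes `profiles.tsv`,
#' `categories.tsv` (explicit zero counts) and `exclusions.tsv` (one row per
#' participant with the failing cells of any excluded one).
#'
#' @param out_dir Study directory.
#' @param config Run configuration; `NULL` reads `config.yaml`.
#' @return A list with `profiles`, `categories`, `inclusion` tibbles
#'   (also written to disk), invisibly.
#' @export
run_classify <- function(out_dir, config = NULL) {
  if (is.null(config)) {
    config <- read_run_config(file.path(out_dir, "config.yaml"))
  }
  an <- config$analysis
  subs <- participant_dirs(out_dir)
  if (length(subs) == 0) abort("No participant directories found.")

  counts <- purrr::map_dfr(subs, function(sub) {
    readr::read_tsv(file.path(sub, "summary.tsv"), show_col_types = FALSE,
                    na = "NA") |>
      filter(trial_type %in% c("go", "stop-success")) |>
      mutate(participant = basename(sub)) |>
      select(participant, modality, trial_type, stim_time_ms, n_meps)
  })
  # a cell with no usable MEPs at all counts as zero, not as a schema error
  counts <- counts |>
    tidyr::complete(participant,
                    tidyr::nesting(modality, trial_type, stim_time_ms),
                    fill = list(n_meps = 0L))
  inclusion <- enforce_inclusion(counts, min_n = an$min_meps)
  readr::write_tsv(inclusion, file.path(out_dir, "exclusions.tsv"), na = "NA")

  included <- inclusion$participant[inclusion$included]
  if (length(included) == 0) abort("No participant passed the inclusion rule.")
  data <- purrr::map_dfr(subs[basename(subs) %in% included], function(sub) {
    ev <- read_events(file.path(sub, "events.tsv"))
    meas <- readr::read_tsv(file.path(sub, "measurements.tsv"),
                            show_col_types = FALSE, na = "NA")
    compute_effect_profiles(meas, ev) |>
      mutate(participant = basename(sub))
  })
  categories <- classify_profiles(data, threshold = an$d_threshold)
  tab <- tabulate_categories(categories)

  readr::write_tsv(data, file.path(out_dir, "profiles.tsv"), na = "NA")
  readr::write_tsv(tab, file.path(out_dir, "categories.tsv"), na = "NA")
  write_stage_manifest(out_dir, "classify", NA,
                       file.path(out_dir, c("profiles.tsv", "categories.tsv",
                                            "exclusions.tsv")))
  invisible(list(profiles = data, categories = tab, inclusion = inclusion))
}

#' Run the full pipeline: simulate, extract, classify
#'
#' @inheritParams run_simulate
#' @return The [run_classify()] result, invisibly.
#' @export
run_pipeline <- function(out_dir, config = default_run_config(),
                         n_participants = 1L, seed = 1L) {
  run_simulate(out_dir, config, n_participants, seed)
  run_extract(out_dir, config)
  invisible(run_classify(out_dir, config))
}
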