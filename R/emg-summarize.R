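#' Baseline-normalized corticospinal excitability
#'
#' @param condition_mean Mean MEP amplitude of a condition cell (mV).
#' @param baseline_mean Mean active-baseline MEP amplitude for the same
#'   effector (mV, `> 0`).
#' @return The ratio `condition_mean / baseline_mean`. Vectorized.
#' @export
normalize_cse <- function(condition_mean, baseline_mean) {
  if (any(!is.finite(baseline_mean)) || any(baseline_mean <= 0)) {
    abort("`baseline_mean` must be finite and > 0.")
  }
  condition_mean / baseline_mean
}

#' Short-interval intracortical inhibition (% inhibition)
#'
#' `SICI = (TS - CS) / TS * 100`, where TS is the mean unconditioned
#' (test-stimulus-only) MEP amplitude and CS the mean conditioned
#' (paired-pulse) amplitude. Larger positive values mean more inhibition;
#' `CS > TS` gives negative values (facilitation), which is allowed.
#'
#' @param mean_test_amp TS mean amplitude (mV, `> 0`).
#' @param mean_conditioned_amp CS mean amplitude (mV).
#' @return Percent inhibition. Vectorized.
#' @export
#' @examples
#' compute_sici(0.8, 0.6) # 25
compute_sici <- function(mean_test_amp, mean_conditioned_amp) {
  if (any(!is.finite(mean_test_amp)) || any(mean_test_amp <= 0)) {
    abort("`mean_test_amp` must be finite and > 0.")
  }
  (mean_test_amp - mean_conditioned_amp) / mean_test_amp * 100
}

# Condition cell labels: go / stop-success / stop-fail task cells keyed by
# stim time, plus per-modality "baseline" (stim_time NA).
condition_cells <- function(events) {
  events |>
    filter(tms_role != "none") |>
    mutate(
      cell = case_when(
        tms_role == "baseline-probe" ~ "baseline",
        trial_type == "go" ~ "go",
        outcome == "stop-success" ~ "stop-success",
        TRUE ~ "stop-fail"
      ),
      stim_time_ms = ifelse(cell == "baseline", NA_real_, stim_time_ms)
    ) |>
    select(trial, modality, cell, stim_time_ms, pulse_type)
}

#' Condition-level summaries: CSE, SICI, CSP
#'
#' Joins accepted MEP measurements to their condition cells
#' (modality x trial type x stim time, plus per-modality active baselines),
#' optionally trims the extreme 5% of amplitudes per cell (the single-pulse
#' study convention; trimming happens after the rejection filters), and
#' returns per-cell means: usable-MEP count, mean amplitude, CSE normalized
#' by the matching single-pulse baseline, SICI (paired-pulse mode only,
#' computed from the cell's unconditioned vs conditioned mean amplitudes,
#' baselines included), and mean silent-period duration where CSP
#' measurements are supplied (manual task, single pulses only).
#'
#' @param measurements Rejection-annotated measurements
#'   ([apply_rejection()] output).
#' @param events Events tibble.
#' @param mode `"exp1"` (single-pulse; trimming on) or `"exp2"`
#'   (single+paired; SICI; trimming off).
#' @param csp Optional [measure_csps()] output.
#' @param trim Override the mode's trimming default.
#' @param tail_fraction Trimmed fraction per tail.
#' @param include_failed_stop Also emit failed-stop cells.
#' @return Tibble with one row per condition cell: `modality`, `trial_type`
#'   (`"baseline"`, `"go"`, `"stop-success"`, optionally `"stop-fail"`),
#'   `stim_time_ms` (`NA` for baselines), `n_meps`, `mean_amplitude_mv`,
#'   `normalized_cse`, `sici_pct`, `mean_csp_ms`, `n_csp`.
#' @export
summarize_conditions <- function(measurements, events,
                                 mode = c("exp1", "exp2"),
                                 csp = NULL,
                                 trim = NULL,
                                 tail_fraction = 0.05,
                                 include_failed_stop = FALSE) {
  mode <- match.arg(mode)
  if (is.null(trim)) trim <- mode == "exp1"
  cells <- condition_cells(events)

  if (!all(measurements$trial %in% cells$trial)) {
    abort("Some measurement trial indices have no matching TMS events row.")
  }
  m <- measurements |>
    filter(!rejected) |>
    left_join(cells, by = "trial")
  if (!include_failed_stop) m <- m |> filter(cell != "stop-fail")

  # rejection filters first, then per-cell extreme-value trimming
  m <- m |>
    group_by(modality, cell, stim_time_ms, pulse_type) |>
    mutate(keep_after_trim = trim_extremes(amplitude_mv, tail_fraction,
                                           enabled = trim)) |>
    ungroup() |>
    filter(keep_after_trim) |>
    select(-"keep_after_trim")

  agg <- m |>
    group_by(modality, cell, stim_time_ms, pulse_type) |>
    summarise(n_meps = n(), mean_amplitude_mv = mean(amplitude_mv),
              .groups = "drop")

  single <- agg |> filter(pulse_type == "single")
  base <- single |>
    filter(cell == "baseline") |>
    select(modality, baseline_mean = mean_amplitude_mv)
  if (nrow(base) == 0 || any(base$baseline_mean <= 0)) {
    abort("Missing or non-positive single-pulse baseline amplitudes.")
  }

  out <- single |>
    left_join(base, by = "modality") |>
    mutate(normalized_cse = normalize_cse(mean_amplitude_mv, baseline_mean)) |>
    select(-baseline_mean, -pulse_type)

  if (mode == "exp2") {
    paired <- agg |>
      filter(pulse_type == "paired") |>
      select(modality, cell, stim_time_ms,
             cs_amp = mean_amplitude_mv, n_paired = n_meps)
    out <- out |>
      left_join(paired, by = c("modality", "cell", "stim_time_ms")) |>
      mutate(sici_pct = ifelse(is.na(cs_amp), NA_real_,
                               compute_sici(mean_amplitude_mv, cs_amp))) |>
      select(-cs_amp, -n_paired)
  } else {
    out$sici_pct <- NA_real_
  }

  if (!is.null(csp)) {
    csp_cells <- csp |>
      filter(present) |>
      left_join(cells, by = "trial") |>
      group_by(modality, cell, stim_time_ms) |>
      summarise(mean_csp_ms = mean(duration_ms), n_csp = n(),
                .groups = "drop")
    out <- out |> left_join(csp_cells, by = c("modality", "cell", "stim_time_ms"))
    out$n_csp[is.na(out$n_csp)] <- 0L
  } else {
    out$mean_csp_ms <- NA_real_
    out$n_csp <- 0L
  }

  out |>
    rename(trial_type = cell) |>
    arrange(modality, factor(trial_type,
                             c("baseline", "go", "stop-success", "stop-fail")),
            stim_time_ms)
}
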