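#' Cohen's d for go vs. successful-stop MEP amplitudes
#'
#' Two-sample pooled-SD Cohen's d, `(mean(go) - mean(stop)) / s_pooled`, so
#' positive values mean suppression on stop trials. The two trial sets are
#' independent samples within a participant, hence the pooled-SD variant.
#'
#' @param go_amplitudes,stop_amplitudes Numeric vectors (`>= 2` values each).
#' @return Cohen's d.
#' @export
cohens_d <- function(go_amplitudes, stop_amplitudes) {
  x <- go_amplitudes[!is.na(go_amplitudes)]
  y <- stop_amplitudes[!is.na(stop_amplitudes)]
  if (length(x) < 2 || length(y) < 2) {
    abort("Need at least 2 values per group.")
  }
  sp <- sqrt(((length(x) - 1) * sd(x)^2 + (length(y) - 1) * sd(y)^2) /
               (length(x) + length(y) - 2))
  if (sp == 0) abort("Zero pooled SD: Cohen's d undefined.")
  (mean(x) - mean(y)) / sp
}

#' Selective suppression adjustment
#'
#' Subtracts, at each timepoint, the non-selective (task-unrelated effector)
#' effect size from the responding-effector effect size, so the result
#' reflects suppression beyond the non-selective component at the same time.
#'
#' @param manual_d,vocal_d Effect-size vectors on the same stim-time grid.
#' @return `manual_d - vocal_d`, elementwise.
#' @export
selective_adjustment <- function(manual_d, vocal_d) {
  if (length(manual_d) != length(vocal_d)) {
    abort("Effect-size vectors are on misaligned time grids.")
  }
  manual_d - vocal_d
}

increase_profile <- function(d, increase) {
  vapply(seq_along(d), function(t) {
    prev <- if (increase == "running-max") {
      max(0, d[seq_len(t - 1L)])
    } else {
      if (t == 1L) 0 else d[t - 1L]
    }
    d[t] - prev
  }, numeric(1))
}

winning_timepoint <- function(d, threshold, increase) {
  inc <- increase_profile(d, increase)
  qual <- which(inc > threshold)
  pool <- if (length(qual) > 0) qual else seq_along(inc)
  pool[which.max(inc[pool])] # ties resolved to the earliest timepoint
}

#' Classify a participant's suppression-timing profile
#'
#' A suppression type (non-selective/global, or selective) is "shown" when
#' any of its timepoints has d above `threshold`. Neither shown gives
#' `"neither"`; one shown gives `"global-only"` / `"selective-only"`. When
#' both are shown, each type's characteristic timepoint is the one with the
#' greatest increase in d relative to previous timepoints (the first
#' timepoint's increase is d itself; increases at or below `threshold`
#' disqualify a timepoint, and if no timepoint qualifies the greatest
#' increase wins regardless; ties go to the earliest timepoint). An earlier
#' global timepoint gives `"global-then-selective"`, a later one
#' `"selective-then-global"`, equal gives `"same-time"`.
#'
#' @param nonselective_d Effect sizes in the task-unrelated effector, one per
#'   stim time (ascending).
#' @param selective_d Adjusted effect sizes ([selective_adjustment()]), same
#'   grid.
#' @param threshold Smallest-effect threshold.
#' @param increase `"running-max"`: each increase is relative to the maximum
#'   of 0 and all earlier d values; `"pairwise"`: relative to the immediately
#'   preceding d.
#' @return One of `"global-then-selective"`, `"selective-then-global"`,
#'   `"same-time"`, `"global-only"`, `"selective-only"`, `"neither"`.
#' @export
classify_participant <- function(nonselective_d, selective_d,
                                 threshold = 0.2,
                                 increase = c("running-max", "pairwise")) {
  increase <- match.arg(increase)
  if (length(nonselective_d) != length(selective_d) ||
      length(nonselective_d) < 2) {
    abort("Need aligned effect-size vectors of length >= 2.")
  }
  if (any(!is.finite(nonselective_d)) || any(!is.finite(selective_d))) {
    abort("Effect-size vectors must be finite.")
  }
  shown_g <- any(nonselective_d > threshold)
  shown_s <- any(selective_d > threshold)
  if (!shown_g && !shown_s) return("neither")
  if (shown_g && !shown_s) return("global-only")
  if (!shown_g && shown_s) return("selective-only")
  tg <- winning_timepoint(nonselective_d, threshold, increase)
  ts <- winning_timepoint(selective_d, threshold, increase)
  if (tg < ts) "global-then-selective"
  else if (tg > ts) "selective-then-global"
  else "same-time"
}

suppression_categories <- c("global-then-selective", "selective-then-global",
                            "same-time", "global-only", "selective-only",
                            "neither")

#' Per-participant effect-size profiles
#'
#' For each participant, modality and stim time, computes Cohen's d between
#' go and successful-stop MEP amplitudes (accepted single-pulse measurements;
#' baseline normalization is scale-invariant for d and therefore not needed),
#' then derives the non-selective profile (task-unrelated effector, i.e. the
#' vocal task for a hand probe) and the selective profile (manual minus vocal
#' at matched times).
#'
#' @param measurements Rejection-annotated measurements, for one participant
#'   or a cohort (an events `participant` column is honored).
#' @param events Matching events tibble.
#' @param probed_modality Modality in which the probed muscle responds.
#' @return Tibble: `participant`, `stim_time_ms`, `nonselective_d`,
#'   `selective_d`.
#' @export
compute_effect_profiles <- function(measurements, events,
                                    probed_modality = "manual") {
  ev <- events
  if (!"participant" %in% names(ev)) ev$participant <- "s01"
  mm <- measurements
  if (!"participant" %in% names(mm)) {
    ids <- unique(ev$participant)
    if (length(ids) > 1) {
      abort("`measurements` needs a `participant` column when `events` holds several participants.")
    }
    mm$participant <- ids
  }
  cells <- ev |>
    filter(tms_role == "task-pulse",
           !is.na(pulse_type), pulse_type == "single",
           trial_type == "go" | outcome == "stop-success") |>
    mutate(cell = ifelse(trial_type == "go", "go", "stop-success")) |>
    select(participant, trial, modality, cell, stim_time_ms)
  mm <- mm |>
    filter(!rejected) |>
    dplyr::inner_join(cells, by = c("participant", "trial"))

  d_tbl <- mm |>
    group_by(participant, modality, stim_time_ms) |>
    summarise(
      d = cohens_d(amplitude_mv[cell == "go"],
                   amplitude_mv[cell == "stop-success"]),
      .groups = "drop"
    )
  wide <- d_tbl |>
    tidyr::pivot_wider(names_from = modality, values_from = d) |>
    arrange(participant, stim_time_ms)
  other <- setdiff(c("manual", "vocal"), probed_modality)
  tibble(
    participant = wide$participant,
    stim_time_ms = wide$stim_time_ms,
    nonselective_d = wide[[other]],
    selective_d = selective_adjustment(wide[[probed_modality]], wide[[other]])
  )
}

#' Classify every participant's profile
#'
#' @param profiles Output of [compute_effect_profiles()].
#' @param ... Passed to [classify_participant()].
#' @return Tibble: `participant`, `category` (factor over all six
#'   categories).
#' @export
classify_profiles <- function(profiles, ...) {
  profiles |>
    arrange(participant, stim_time_ms) |>
    group_by(participant) |>
    summarise(category = classify_participant(nonselective_d, selective_d, ...),
              .groups = "drop") |>
    mutate(category = factor(category, levels = suppression_categories))
}

#' Tabulate suppression categories
#'
#' @param profiles Either [classify_profiles()] output (with a `category`
#'   column) or [compute_effect_profiles()] output (classified first with
#'   default settings).
#' @param ... Passed to [classify_participant()] when classification is
#'   needed.
#' @return Tibble with one row per category (zeros listed explicitly):
#'   `category`, `n`, `pct`.
#' @export
tabulate_categories <- function(profiles, ...) {
  if (!"category" %in% names(profiles)) {
    profiles <- classify_profiles(profiles, ...)
  }
  if (nrow(profiles) == 0) abort("Need at least one profile.")
  profiles |>
    mutate(category = factor(category, levels = suppression_categories)) |>
    dplyr::count(category, .drop = FALSE) |>
    mutate(pct = 100 * n / sum(n))
}
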