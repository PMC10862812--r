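#' Apply the automatic MEP rejection rules
#'
#' A measurement is rejected when (in this order of recorded reason):
#' the MEP amplitude is below `amp_min_mv` (`small-mep`); the pre-pulse RMS
#' exceeds `rms_max_mv` (`prepulse-emg`); or, on task pulses of responded
#' trials, the response occurred at or before the pulse
#' (`rt-at-or-before-pulse`), i.e. the MEP window is contaminated by the
#' voluntary response. Baseline probes are delivered in the inter-trial
#' interval and are exempt from the RT rule. The function is idempotent:
#' re-applying it does not change the outcome.
#'
#' @param measurements Output of [measure_meps()].
#' @param events Events tibble (for `rt_ms` and `tms_role`).
#' @param amp_min_mv Minimum acceptable MEP amplitude (mV).
#' @param rms_max_mv Maximum acceptable pre-pulse RMS (mV).
#' @return `measurements` with `rejected` (logical) and `reject_reason`
#'   (`"small-mep"`, `"prepulse-emg"`, `"rt-at-or-before-pulse"`, `"none"`).
#' @export
apply_rejection <- function(measurements, events,
                            amp_min_mv = 0.05, rms_max_mv = 0.05) {
  ev <- events |> select(trial, rt_ms, tms_role)
  m <- measurements |>
    select(-dplyr::any_of(c("rejected", "reject_reason", "rt_ms", "tms_role"))) |>
    left_join(ev, by = "trial")
  m |>
    mutate(
      reject_reason = case_when(
        amplitude_mv < amp_min_mv ~ "small-mep",
        prepulse_rms_mv > rms_max_mv ~ "prepulse-emg",
        tms_role == "task-pulse" & !is.na(rt_ms) & !is.na(pulse_time_ms) &
          rt_ms <= pulse_time_ms ~ "rt-at-or-before-pulse",
        TRUE ~ "none"
      ),
      rejected = reject_reason != "none"
    ) |>
    select(-rt_ms, -tms_role)
}

#' Trim extreme MEP amplitudes within a condition
#'
#' Removes the `floor(n * tail_fraction)` smallest and largest values of a
#' condition's amplitude set (so 10 values at the default 5% lose none, 20
#' lose one per tail). Ties are broken by position via the sort order.
#'
#' @param amplitudes Numeric vector.
#' @param tail_fraction Fraction trimmed from each tail.
#' @param enabled If `FALSE`, returns an all-`TRUE` mask (the paired-pulse
#'   study mode, where trimming is not applied).
#' @return Logical keep-mask aligned with `amplitudes`.
#' @export
trim_extremes <- function(amplitudes, tail_fraction = 0.05, enabled = TRUE) {
  n <- length(amplitudes)
  if (n == 0) abort("Empty amplitude set.")
  keep <- rep(TRUE, n)
  if (!enabled) return(keep)
  k <- floor(n * tail_fraction)
  if (k > 0) {
    ord <- order(amplitudes)
    keep[ord[seq_len(k)]] <- FALSE
    keep[ord[seq(n - k + 1L, n)]] <- FALSE
  }
  keep
}

#' Participant-level inclusion by usable-MEP counts
#'
#' A participant is included when every required condition cell has at least
#' `min_n` usable measurements (15 in the single-pulse study, 10 in the
#' paired-pulse study, 5 for failed-stop silent periods).
#'
#' @param counts Tibble with a `participant` column, one or more cell-label
#'   columns, and a count column `n_col`. Every participant must carry every
#'   cell (no missing combinations).
#' @param min_n Per-cell inclusion threshold.
#' @param n_col Name of the count column.
#' @return Tibble: `participant`, `included`, `n_failing`, `failing_cells`
#'   (comma-separated labels of cells below threshold).
#' @export
enforce_inclusion <- function(counts, min_n = 15, n_col = "n_meps") {
  stopifnot("participant" %in% names(counts), n_col %in% names(counts))
  cell_cols <- setdiff(names(counts), c("participant", n_col))
  full <- counts |>
    distinct(dplyr::across(dplyr::all_of(cell_cols)))
  by_p <- split(counts, counts$participant)
  rows <- purrr::map(names(by_p), function(p) {
    d <- by_p[[p]]
    if (nrow(dplyr::anti_join(full, d, by = cell_cols)) > 0) {
      abort(sprintf("Participant %s is missing required condition cells.", p))
    }
    if (any(is.na(d[[n_col]]))) {
      abort(sprintf("Participant %s has missing counts.", p))
    }
    fail <- d[d[[n_col]] < min_n, , drop = FALSE]
    lab <- if (nrow(fail) == 0) "" else {
      paste(apply(fail[cell_cols], 1, paste, collapse = "/"), collapse = ", ")
    }
    tibble(participant = p, included = nrow(fail) == 0,
           n_failing = nrow(fail), failing_cells = lab)
  })
  bind_rows(rows)
}
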