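#' Draw ex-Gaussian go finishing times
#'
#' @param n Number of draws.
#' @param params A [race_params()].
#' @return Numeric vector of finishing times (ms).
#' @keywords internal
rexgauss <- function(n, params) {
  g <- rnorm(n, params$go_mu, params$go_sigma)
  if (params$go_tau > 0) g <- g + rexp(n, rate = 1 / params$go_tau)
  g
}

#' Simulate one stop-signal race
#'
#' Runs the independent horse race for a single stop trial: the go process
#' finishes at an ex-Gaussian time; the stop process, when it triggers
#' (probability `1 - trigger_failure_p`), wins iff `ssd + ssrt_true` precedes
#' the go finishing time. A response is emitted only if the go process wins
#' and finishes inside the response window; a stop trial without an emitted
#' response is scored as a successful stop (as it would be observationally).
#'
#' @param params A [race_params()].
#' @param ssd_ms Stop-signal delay (ms), `>= 0`.
#' @param response_window_ms Response deadline (ms).
#' @return A list with `outcome` (`"stop-success"` or `"stop-fail"`), `rt_ms`
#'   (`NA` for successful stops), and `go_ft` (the latent go finishing time).
#' @export
simulate_race_trial <- function(params, ssd_ms,
                                response_window_ms = 1000) {
  stopifnot(ssd_ms >= 0)
  go_ft <- rexgauss(1L, params)
  triggered <- runif(1L) >= params$trigger_failure_p
  stop_wins <- triggered && (ssd_ms + params$ssrt_true < go_ft)
  responded <- !stop_wins && go_ft <= response_window_ms
  list(
    outcome = if (responded) "stop-fail" else "stop-success",
    rt_ms = if (responded) go_ft else NA_real_,
    go_ft = go_ft
  )
}

#' Update one SSD staircase tracker
#'
#' The standard 1-up/1-down tracking rule: a successful stop makes the next
#' stop harder (`+step`), a failed stop makes it easier (`-step`). The SSD is
#' clamped to `[0, response_window - step]`.
#'
#' @param ssd_ms Current SSD (ms).
#' @param outcome `"stop-success"` or `"stop-fail"`.
#' @param step_ms Staircase step (ms).
#' @param response_window_ms Response deadline (ms).
#' @return The updated SSD (ms).
#' @export
update_staircase <- function(ssd_ms, outcome, step_ms = 50,
                             response_window_ms = 1000) {
  outcome <- match.arg(outcome, c("stop-success", "stop-fail"))
  new_ssd <- if (outcome == "stop-success") ssd_ms + step_ms else ssd_ms - step_ms
  min(max(new_ssd, 0), response_window_ms - step_ms)
}

#' Simulate task behavior over a trial sequence
#'
#' Walks a trial-skeleton table in order, drawing go finishing times from the
#' modality's race parameters and racing the stop process on stop trials.
#' SSDs follow independent 1-up/1-down staircases per (modality, response)
#' cell, all initialized at `ssd_init_ms`. Stop-trial pulse times are set to
#' `ssd + stim_time` (probes are time-locked to the stop signal).
#'
#' @param trials A trial-skeleton tibble from [generate_trial_sequence()].
#' @param race Named list with elements `manual` and `vocal`, each a
#'   [race_params()].
#' @param config The [design_config()] used to build `trials`.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return The trials tibble with `ssd_ms`, `rt_ms`, `outcome`, `response`
#'   and stop-trial `tms_time_ms` filled.
#' @export
simulate_behavior <- function(trials,
                              race = list(manual = race_params_manual(),
                                          vocal = race_params_vocal()),
                              config = exp1_design(),
                              seed = NULL) {
  stopifnot(all(c("manual", "vocal") %in% names(race)))
  run <- function() {
    n <- nrow(trials)
    modality <- trials$modality
    type <- trials$trial_type
    stim <- trials$stim_time_ms
    window <- config$response_window_ms
    step <- config$ssd_step_ms

    response <- sample.int(2L, n, replace = TRUE)
    go_ft <- numeric(n)
    for (m in c("manual", "vocal")) {
      idx <- modality == m
      go_ft[idx] <- rexgauss(sum(idx), race[[m]])
    }
    trig <- matrix(runif(n), ncol = 1)

    ssd <- rep(NA_real_, n)
    rt <- rep(NA_real_, n)
    outcome <- character(n)
    tms_time <- trials$tms_time_ms
    # trackers[modality, response]
    trackers <- matrix(config$ssd_init_ms, nrow = 2, ncol = 2,
                       dimnames = list(c("manual", "vocal"), NULL))

    for (i in seq_len(n)) {
      if (type[i] == "go") {
        if (go_ft[i] <= window) {
          rt[i] <- go_ft[i]
          outcome[i] <- "go-correct"
        } else {
          outcome[i] <- "go-omission"
        }
      } else {
        m <- modality[i]
        r <- response[i]
        ssd[i] <- trackers[m, r]
        triggered <- trig[i] >= race[[m]]$trigger_failure_p
        stop_wins <- triggered && (ssd[i] + race[[m]]$ssrt_true < go_ft[i])
        responded <- !stop_wins && go_ft[i] <= window
        if (responded) {
          rt[i] <- go_ft[i]
          outcome[i] <- "stop-fail"
        } else {
          outcome[i] <- "stop-success"
        }
        trackers[m, r] <- update_staircase(ssd[i], outcome[i], step, window)
        if (!is.na(stim[i])) tms_time[i] <- ssd[i] + stim[i]
      }
    }

    out <- trials
    out$ssd_ms <- ssd
    out$rt_ms <- rt
    out$outcome <- outcome
    out$tms_time_ms <- tms_time
    out$response <- response
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate one participant end to end (behavior only)
#'
#' @param config A [design_config()]; its seed controls both the sequence and
#'   the behavioral randomness.
#' @param race As in [simulate_behavior()].
#' @return Events tibble.
#' @export
simulate_participant <- function(config = exp1_design(),
                                 race = list(manual = race_params_manual(),
                                             vocal = race_params_vocal())) {
  trials <- generate_trial_sequence(config)
  simulate_behavior(trials, race, config, seed = config$seed + 10^6L)
}

#' Simulate a cohort of participants (behavior only)
#'
#' Each participant gets an independently seeded trial sequence and behavior,
#' derived deterministically from `seed`.
#'
#' @param n_participants Cohort size.
#' @param config Base [design_config()] (its own seed is replaced per
#'   participant).
#' @param race As in [simulate_behavior()].
#' @param seed Cohort master seed.
#' @return Events tibble with a leading `participant` column
#'   (`"s01", "s02", ...`).
#' @export
simulate_cohort <- function(n_participants,
                            config = exp1_design(),
                            race = list(manual = race_params_manual(),
                                        vocal = race_params_vocal()),
                            seed = 1L) {
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max - 1L, n_participants))
  purrr::map_dfr(seq_len(n_participants), function(p) {
    cfg <- config
    cfg$seed <- seeds[p]
    ev <- simulate_participant(cfg, race)
    dplyr::bind_cols(tibble(participant = sprintf("s%02d", p)), ev)
  })
}
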