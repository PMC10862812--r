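#' Generate the trial sequence for a session
#'
#' Builds the ordered table of trial skeletons for one participant-session.
#' Within every block, exactly `trials_per_block * stop_fraction` trials are
#' stop trials; every stop trial carries a task TMS pulse, an equal number of
#' go trials carry task pulses, and an equal number of go trials are dedicated
#' baseline-probe trials (TMS delivered in the inter-trial interval before
#' their go signal, so the probe requires the preceding trial to be a go
#' trial). Probe latencies are balanced exactly within block for each trial
#' type. Modality alternates across blocks; in paired-pulse mode the pulse
#' type alternates in pairs of blocks.
#'
#' @param config A [design_config()].
#' @return A tibble of trial skeletons with columns `trial`, `block`,
#'   `modality`, `trial_type`, `ssd_ms`, `rt_ms`, `outcome`, `tms_role`,
#'   `tms_time_ms`, `pulse_type`, `stim_time_ms`. `ssd_ms`, `rt_ms`,
#'   `outcome` and stop-trial `tms_time_ms` are `NA` until filled by
#'   [simulate_behavior()]. For baseline probes `tms_time_ms` is the probe
#'   latency after the preceding trial's end and `stim_time_ms` is `NA`.
#' @export
generate_trial_sequence <- function(config) {
  stopifnot(inherits(config, "design_config"))
  tpb <- config$trials_per_block
  n_stop <- as.integer(round(tpb * config$stop_fraction))
  n_go <- tpb - n_stop
  n_stim <- length(config$stim_times_ms)
  n_probe <- length(config$baseline_probe_times_ms)

  if (n_stop %% n_stim != 0L) {
    abort(sprintf(
      "Invalid design: %d stop trials per block cannot be balanced over %d stim times.",
      n_stop, n_stim), class = "stopphys_invalid_design")
  }
  if (n_stop %% n_probe != 0L) {
    abort(sprintf(
      "Invalid design: %d baseline probes per block cannot be balanced over %d probe times.",
      n_stop, n_probe), class = "stopphys_invalid_design")
  }
  if (n_go < 2L * n_stop) {
    abort(sprintf(
      "Invalid design: need >= %d go trials per block (task pulses + baseline probes), have %d.",
      2L * n_stop, n_go), class = "stopphys_invalid_design")
  }

  modalities <- if (config$modality_order == "manual-first") {
    c("manual", "vocal")
  } else {
    c("vocal", "manual")
  }
  block_modality <- modalities[((seq_len(config$n_blocks) - 1L) %% 2L) + 1L]
  block_pulse <- if (config$paired_pulse) {
    c("single", "paired")[((ceiling(seq_len(config$n_blocks) / 2) - 1L) %% 2L) + 1L]
  } else {
    rep("single", config$n_blocks)
  }

  withr::with_seed(config$seed, {
    blocks <- purrr::map(seq_len(config$n_blocks), function(b) {
      build_block(b, block_modality[b], block_pulse[b],
                  tpb, n_stop, config)
    })
  })

  out <- bind_rows(blocks)
  out$trial <- seq_len(nrow(out))
  out
}

# One block: rejection-sample an ordering with enough go-after-go positions
# for the baseline probes, then assign pulse roles and balanced probe times.
build_block <- function(block, modality, pulse_type, tpb, n_stop, config) {
  n_go <- tpb - n_stop
  for (attempt in seq_len(1000L)) {
    types <- sample(rep(c("stop", "go"), c(n_stop, n_go)))
    eligible <- which(types == "go" &
                        c(FALSE, types[-length(types)] == "go"))
    if (length(eligible) >= n_stop) break
    if (attempt == 1000L) {
      abort("Invalid design: cannot place baseline probes on consecutive-go positions.",
            class = "stopphys_invalid_design")
    }
  }

  probe_pos <- if (n_stop > 0) resample(eligible, n_stop) else integer()
  go_pos <- setdiff(which(types == "go"), probe_pos)
  task_go_pos <- resample(go_pos, n_stop)
  stop_pos <- which(types == "stop")

  stim_each <- n_stop %/% length(config$stim_times_ms)
  probe_each <- n_stop %/% length(config$baseline_probe_times_ms)

  stim_time <- rep(NA_real_, tpb)
  stim_time[stop_pos] <- sample(rep(config$stim_times_ms, stim_each))
  stim_time[task_go_pos] <- sample(rep(config$stim_times_ms, stim_each))

  tms_role <- rep("none", tpb)
  tms_role[stop_pos] <- "task-pulse"
  tms_role[task_go_pos] <- "task-pulse"
  tms_role[probe_pos] <- "baseline-probe"

  tms_time <- rep(NA_real_, tpb)
  # go task pulses fire at the stim time after go onset; stop-trial pulse
  # times depend on the SSD and are filled during simulation
  tms_time[task_go_pos] <- stim_time[task_go_pos]
  tms_time[probe_pos] <- sample(rep(config$baseline_probe_times_ms, probe_each))

  tibble(
    block = block,
    modality = modality,
    trial_type = types,
    ssd_ms = NA_real_,
    rt_ms = NA_real_,
    outcome = NA_character_,
    tms_role = tms_role,
    tms_time_ms = tms_time,
    pulse_type = ifelse(tms_role == "none", NA_character_, pulse_type),
    stim_time_ms = stim_time
  )
}

# sample() without the scalar-x surprise
resample <- function(x, size) x[sample.int(length(x), size)]
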