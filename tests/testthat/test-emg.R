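test_that("artifact localization finds scheduled and jittered pulses", {
  sr <- 5000
  trace <- rnorm(4000, 0, 0.005)
  trace[2000] <- 2
  res <- find_tms_artifact(trace, 2000, sr)
  expect_equal(res$pulse_sample, 2000)
  expect_true(res$confident)
  # artifact jittered +2 ms (10 samples)
  trace2 <- rnorm(4000, 0, 0.005)
  trace2[2010] <- 2
  res2 <- find_tms_artifact(trace2, 2000, sr)
  expect_equal(res2$pulse_sample, 2010)
  # flat trace: low confidence
  expect_false(find_tms_artifact(rep(0, 4000), 2000, sr)$confident)
  expect_error(find_tms_artifact(trace, 10, sr))
})

test_that("MEP amplitude is max minus min over the closed 10-50 ms window", {
  sr <- 1000
  trace <- rep(0, 400)
  trace[120] <- 0.30   # 19 ms after a pulse at sample 101
  trace[140] <- -0.20
  expect_equal(extract_mep(trace, 101, sr), 0.50)
  expect_equal(extract_mep(rep(0, 400), 101, sr), 0)
  # endpoints are included
  tr2 <- rep(0, 400)
  tr2[101 + 10] <- 0.4   # exactly 10 ms
  tr2[101 + 50] <- -0.1  # exactly 50 ms
  expect_equal(extract_mep(tr2, 101, sr), 0.5)
  expect_error(extract_mep(trace, 380, sr))
})

test_that("pre-pulse RMS matches closed forms", {
  sr <- 1000
  expect_equal(prepulse_rms(rep(0.05, 200), 150, sr), 0.05)
  expect_equal(prepulse_rms(rep(0, 200), 150, sr), 0)
  # sine of amplitude a over whole cycles: RMS = a / sqrt(2)
  a <- 0.7
  t <- seq_len(400)
  sine <- a * sin(2 * pi * 100 * t / sr)  # 100 Hz -> 8 cycles in 80 ms
  expect_equal(prepulse_rms(sine, 201, sr, span_ms = 80), a / sqrt(2))
  expect_error(prepulse_rms(sine, 50, sr))
})

test_that("the RT-overlap rule rejects at and before the pulse but not after", {
  events <- tibble::tibble(
    trial = 1:4,
    rt_ms = c(250, 240, 500, 250),
    tms_role = c("task-pulse", "task-pulse", "task-pulse", "baseline-probe")
  )
  m <- tibble::tibble(
    trial = 1:4,
    pulse_time_ms = c(250, 250, 150, NA),
    amplitude_mv = 0.5,
    prepulse_rms_mv = 0.01,
    artifact_confident = TRUE
  )
  r <- apply_rejection(m, events)
  expect_equal(r$reject_reason,
               c("rt-at-or-before-pulse", "rt-at-or-before-pulse",
                 "none", "none"))
  # baseline probes (inter-trial pulses) are exempt from the RT rule
  expect_false(r$rejected[4])
})

test_that("the constructed 10-trial fixture yields exactly 4 rejections", {
  events <- tibble::tibble(
    trial = 1:10,
    rt_ms = c(rep(NA, 6), 500, 250, NA, NA),
    tms_role = c(rep("task-pulse", 9), "baseline-probe")
  )
  m <- tibble::tibble(
    trial = 1:10,
    pulse_time_ms = c(rep(150, 7), 250, 150, NA),
    amplitude_mv = c(0.04, 0.02, rep(0.5, 8)),
    prepulse_rms_mv = c(rep(0.01, 3), 0.06, rep(0.01, 6)),
    artifact_confident = TRUE
  )
  r <- apply_rejection(m, events)
  expect_equal(sum(r$rejected), 4)
  expect_equal(sum(r$reject_reason == "small-mep"), 2)
  expect_equal(sum(r$reject_reason == "prepulse-emg"), 1)
  expect_equal(sum(r$reject_reason == "rt-at-or-before-pulse"), 1)
  expect_true(all(xor(r$rejected, r$reject_reason == "none")))
  # precedence: a trial violating both thresholds records the amplitude reason
  m2 <- m
  m2$prepulse_rms_mv[1] <- 0.2
  expect_equal(apply_rejection(m2, events)$reject_reason[1], "small-mep")
  # idempotence
  expect_identical(apply_rejection(r, events), r)
})

test_that("extreme-value trimming follows the floor rule", {
  expect_equal(sum(trim_extremes(1:20)), 18)
  expect_equal(sum(trim_extremes(1:10)), 10)   # floor(10 * .05) = 0
  expect_true(all(trim_extremes(1:20, enabled = FALSE)))
  keep <- trim_extremes(c(5, 1, 3, 100, 2, 4, 6, 7, 8, 9,
                          10, 11, 12, 13, 14, 15, 16, 17, 18, 0.5))
  expect_false(keep[4])   # largest dropped
  expect_false(keep[20])  # smallest dropped
  expect_error(trim_extremes(numeric(0)))
})

test_that("inclusion requires every cell at threshold", {
  counts <- tidyr::crossing(participant = c("a", "b"),
                            modality = c("manual", "vocal"),
                            trial_type = c("go", "stop-success"),
                            stim_time_ms = c(150, 250))
  counts$n_meps <- 15
  counts$n_meps[counts$participant == "b" &
                  counts$modality == "vocal" &
                  counts$trial_type == "stop-success" &
                  counts$stim_time_ms == 250] <- 14
  inc <- enforce_inclusion(counts, min_n = 15)
  expect_true(inc$included[inc$participant == "a"])
  expect_false(inc$included[inc$participant == "b"])
  expect_match(inc$failing_cells[inc$participant == "b"],
               "vocal/stop-success/250")
  # the failed-stop threshold of 10 admits cells of exactly 10
  expect_true(all(enforce_inclusion(dplyr::mutate(counts, n_meps = 10),
                                    min_n = 10)$included))
  expect_error(enforce_inclusion(counts[-1, ], min_n = 15))
})

test_that("CSE normalization and SICI follow their defining formulas", {
  expect_equal(normalize_cse(1.2, 1.2), 1)
  expect_equal(normalize_cse(0.5, 1.0), 0.5)
  expect_error(normalize_cse(1, 0))
  expect_equal(compute_sici(1, 1), 0)
  expect_equal(compute_sici(1, 0), 100)
  expect_equal(compute_sici(0.8, 0.6), 25)
  expect_lt(compute_sici(1, 1.2), 0)  # facilitation allowed
  expect_error(compute_sici(0, 0.5))
  # complement identity: inhibition% + (CS/TS)*100 = 100 exactly
  ts <- c(1, 0.8, 2.5); cs <- c(0.4, 0.6, 2.5)
  expect_equal(compute_sici(ts, cs) + cs / ts * 100, rep(100, 3))
})

test_that("condition summaries enumerate the design cells", {
  s <- sim_session(config = design_config(n_blocks = 4, trials_per_block = 45,
                                          seed = 11), seed = 42)
  summ <- summarize_conditions(s$measurements, s$events, mode = "exp1")
  expect_equal(nrow(summ), 14)  # 2 baselines + 2 x 2 x 3 task cells
  expect_equal(sum(summ$trial_type == "baseline"), 2)
  expect_true(all(is.na(summ$sici_pct)))
  # baselines normalize to exactly 1 against themselves
  expect_equal(summ$normalized_cse[summ$trial_type == "baseline"], c(1, 1))

  s2 <- sim_session(config = exp2_design(n_blocks = 4, trials_per_block = 36,
                                         seed = 3), seed = 5)
  summ2 <- summarize_conditions(s2$measurements, s2$events, mode = "exp2")
  expect_equal(nrow(summ2), 10)  # no 200-ms cells
  expect_false(any(summ2$stim_time_ms == 200, na.rm = TRUE))
  expect_true(all(is.finite(summ2$sici_pct)))

  bad <- s$measurements
  bad$trial[1] <- 99999
  expect_error(summarize_conditions(bad, s$events, mode = "exp1"))
})

test_that("noiseless synthesis reproduces injected scalings through the pipeline", {
  s <- sim_session(config = tiny_design(seed = 7), synth = noiseless_synth(),
                   seed = 1)
  acc <- dplyr::filter(s$measurements, !rejected)
  tru <- s$traces$truth
  j <- dplyr::inner_join(acc, tru, by = "trial")
  expect_equal(j$amplitude_mv, j$mep_amp_mv, tolerance = 1e-12)

  summ <- summarize_conditions(s$measurements, s$events, mode = "exp1",
                               trim = FALSE)
  cells <- dplyr::inner_join(
    j, stopphys:::condition_cells(s$events), by = "trial")
  expected <- cells |>
    dplyr::group_by(modality, cell, stim_time_ms) |>
    dplyr::summarise(truth_cse = mean(scaling), .groups = "drop")
  got <- dplyr::inner_join(
    summ, expected,
    by = c("modality", "trial_type" = "cell", "stim_time_ms"))
  expect_gt(nrow(got), 10)
  expect_equal(got$normalized_cse, got$truth_cse, tolerance = 1e-12)
})
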