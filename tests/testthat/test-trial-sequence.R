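test_that("the full design produces the canonical trial and pulse counts", {
  tr <- generate_trial_sequence(exp1_design(seed = 3))
  expect_equal(nrow(tr), 1080)
  expect_equal(sum(tr$trial_type == "stop"), 360)
  expect_equal(sum(tr$trial_type == "stop" & tr$tms_role == "task-pulse"), 360)
  expect_equal(sum(tr$trial_type == "go" & tr$tms_role == "task-pulse"), 360)
  expect_equal(sum(tr$tms_role == "baseline-probe"), 360)
  # stim times balanced exactly within each trial type
  tab <- table(tr$stim_time_ms, tr$trial_type)
  expect_true(all(tab == 120))
  # probe latencies balanced exactly
  probes <- tr$tms_time_ms[tr$tms_role == "baseline-probe"]
  expect_equal(as.integer(table(probes)), rep(120L, 3))
})

test_that("sequence balance holds across a range of valid designs", {
  configs <- list(
    design_config(n_blocks = 1, trials_per_block = 9, seed = 5),
    design_config(n_blocks = 3, trials_per_block = 36, seed = 6),
    exp2_design(n_blocks = 4, trials_per_block = 36, seed = 7),
    design_config(n_blocks = 2, trials_per_block = 45, seed = 8,
                  modality_order = "vocal-first")
  )
  for (cfg in configs) {
    tr <- generate_trial_sequence(cfg)
    n_stop_expected <- cfg$n_blocks * cfg$trials_per_block * cfg$stop_fraction
    expect_equal(sum(tr$trial_type == "stop"), n_stop_expected)
    # per-type stim-time counts differ by zero
    tab <- table(tr$stim_time_ms, tr$trial_type)
    expect_true(all(tab == tab[1, 1]))
    # every baseline probe sits on a consecutive-go position
    probe_idx <- which(tr$tms_role == "baseline-probe")
    expect_true(all(tr$trial_type[probe_idx] == "go"))
    expect_true(all(tr$trial_type[probe_idx - 1] == "go"))
    expect_true(all(tr$block[probe_idx - 1] == tr$block[probe_idx]))
    # modality alternates by block in the configured order
    first <- if (cfg$modality_order == "manual-first") "manual" else "vocal"
    expect_equal(unique(tr$modality[tr$block == 1]), first)
    if (cfg$n_blocks >= 2) {
      expect_equal(length(unique(tr$modality[tr$block == 2])), 1L)
      expect_false(unique(tr$modality[tr$block == 2]) == first)
    }
  }
})

test_that("the smallest balanced design has 3 stop trials with one pulse per stim time", {
  tr <- generate_trial_sequence(design_config(n_blocks = 1, trials_per_block = 9,
                                              seed = 2))
  expect_equal(nrow(tr), 9)
  expect_equal(sum(tr$trial_type == "stop"), 3)
  stim_stop <- tr$stim_time_ms[tr$trial_type == "stop"]
  expect_equal(sort(stim_stop), c(150, 200, 250))
})

test_that("the same seed reproduces the sequence exactly", {
  cfg <- exp1_design(seed = 42)
  expect_identical(generate_trial_sequence(cfg), generate_trial_sequence(cfg))
})

test_that("unbalanceable designs raise an invalid-design error", {
  expect_error(design_config(trials_per_block = 10, stop_fraction = 1 / 3),
               class = "stopphys_invalid_design")
  # 10 stop trials per block cannot split over 3 stim times
  expect_error(
    generate_trial_sequence(design_config(n_blocks = 1, trials_per_block = 30,
                                          seed = 1)),
    class = "stopphys_invalid_design")
  # stop_fraction 1/2 leaves no room for probes + go pulses
  expect_error(
    generate_trial_sequence(design_config(n_blocks = 1, trials_per_block = 6,
                                          stop_fraction = 0.5, seed = 1)),
    class = "stopphys_invalid_design")
  expect_error(design_config(stim_times_ms = c(250, 150)),
               class = "stopphys_invalid_design")
  expect_error(design_config(ssd_step_ms = 0),
               class = "stopphys_invalid_design")
})

test_that("paired-pulse mode alternates pulse type in pairs of blocks", {
  tr <- generate_trial_sequence(exp2_design(n_blocks = 8, trials_per_block = 18,
                                            seed = 9))
  mode_by_block <- tapply(tr$pulse_type[tr$tms_role != "none"],
                          tr$block[tr$tms_role != "none"],
                          function(x) unique(x))
  expect_equal(as.character(mode_by_block),
               rep(c("single", "single", "paired", "paired"), 2))
  expect_false(any(tr$stim_time_ms == 200, na.rm = TRUE))
})
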