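test_that("staircase follows the 1-up/1-down rule with clamping", {
  expect_equal(update_staircase(200, "stop-success"), 250)
  expect_equal(update_staircase(200, "stop-fail"), 150)
  expect_equal(update_staircase(0, "stop-fail"), 0)
  expect_equal(update_staircase(950, "stop-success"), 950)
  # alternating outcomes oscillate between two levels
  ssd <- 200
  path <- numeric(6)
  for (i in 1:6) {
    out <- if (i %% 2 == 1) "stop-success" else "stop-fail"
    ssd <- update_staircase(ssd, out)
    path[i] <- ssd
  }
  expect_equal(path, c(250, 200, 250, 200, 250, 200))
})

test_that("race outcomes respect the limit cases", {
  p <- race_params(500, 50, 50, 200)
  set.seed(1)
  # stop cannot win with an enormous SSD: always a failed stop with rt = go RT
  res <- replicate(50, simulate_race_trial(p, 1e6, response_window_ms = Inf),
                   simplify = FALSE)
  expect_true(all(vapply(res, `[[`, "", "outcome") == "stop-fail"))
  expect_equal(vapply(res, `[[`, 0, "rt_ms"), vapply(res, `[[`, 0, "go_ft"))

  # instantaneous stop process: success probability tends to 1 - p(trigger failure)
  p_tf <- race_params(500, 50, 50, ssrt_true = 1e-6, trigger_failure_p = 0.3)
  set.seed(2)
  out <- replicate(4000, simulate_race_trial(p_tf, 0)$outcome)
  expect_equal(mean(out == "stop-success"), 0.7, tolerance = 0.05)

  expect_error(simulate_race_trial(p, -5))
})

test_that("stop-success probability matches the closed-form ex-Gaussian tail", {
  # oracle: P(success) = P(go finishing time > ssd + ssrt)
  p <- race_params(500, 50, 50, 200)
  p_success_true <- 1 - pexgauss(300 + 200, 500, 50, 50)
  set.seed(7)
  out <- replicate(1e5, simulate_race_trial(p, 300)$outcome)
  p_hat <- mean(out == "stop-success")
  se <- sqrt(p_success_true * (1 - p_success_true) / 1e5)
  expect_lt(abs(p_hat - p_success_true), 4 * se)
})

test_that("simulated sessions are deterministic and internally consistent", {
  cfg <- tiny_design(seed = 11)
  tr <- generate_trial_sequence(cfg)
  ev1 <- simulate_behavior(tr, config = cfg, seed = 99)
  ev2 <- simulate_behavior(tr, config = cfg, seed = 99)
  expect_identical(ev1, ev2)

  # outcome bookkeeping is conserved
  expect_equal(sum(ev1$outcome %in% c("go-correct", "go-omission",
                                      "stop-success", "stop-fail")),
               nrow(ev1))
  # stop trials carry an SSD; successful stops carry no RT
  stops <- ev1[ev1$trial_type == "stop", ]
  expect_true(all(!is.na(stops$ssd_ms)))
  expect_true(all(is.na(stops$rt_ms[stops$outcome == "stop-success"])))
  expect_true(all(!is.na(stops$rt_ms[stops$outcome == "stop-fail"])))
  # stop-trial pulses fire at ssd + stim time
  expect_equal(stops$tms_time_ms, stops$ssd_ms + stops$stim_time_ms)
  # RTs inside the response window
  expect_true(all(ev1$rt_ms <= cfg$response_window_ms, na.rm = TRUE))
})

test_that("the staircase tracks p(inhibit) near one half over a cohort", {
  ev <- simulate_cohort(6, exp1_design(), seed = 33)
  b <- summarize_behavior(ev)
  expect_lt(abs(mean(b$p_inhibit) - 0.5), 0.03)
  expect_true(all(b$p_inhibit > 0.4 & b$p_inhibit < 0.6))
})

test_that("failed-stop RTs are faster than go RTs for every simulated participant", {
  ev <- simulate_cohort(4, design_config(n_blocks = 4, trials_per_block = 45,
                                         seed = 2), seed = 13)
  b <- summarize_behavior(ev)
  expect_true(all(b$mean_failed_stop_rt < b$mean_go_rt))
})
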