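test_that("voice onset detection returns the first strict threshold crossing", {
  sr <- 1000
  env <- c(rep(0.01, 420), rep(0.8, 100))
  expect_equal(detect_voice_onset(env, 0.05, sr), 420)
  expect_true(is.na(detect_voice_onset(rep(0.01, 500), 0.05, sr)))
  # two bursts: the first crossing wins
  env2 <- rep(0.01, 1000)
  env2[301:350] <- 0.9
  env2[601:650] <- 0.9
  expect_equal(detect_voice_onset(env2, 0.05, sr), 300)
  expect_error(detect_voice_onset(c(0.1, NA), 0.05, sr))
  expect_error(detect_voice_onset(numeric(0), 0.05, sr))
})

test_that("raising the onset threshold never decreases the detected RT", {
  set.seed(9)
  sr <- 1000
  for (i in 1:20) {
    env <- abs(rnorm(800, 0, 0.2)) + c(rep(0, 400), seq(0, 2, length.out = 400))
    rts <- vapply(c(0.1, 0.3, 0.6, 1.0), function(th) {
      r <- detect_voice_onset(env, th, sr)
      if (is.na(r)) Inf else r
    }, numeric(1))
    expect_true(all(diff(rts) >= 0))
  }
})

test_that("integration-method SSRT matches hand-computed cases", {
  # constant go distribution
  expect_equal(compute_ssrt_integration(rep(500, 10), 0, 0.5, 300), 200)
  # evenly spaced RTs: rank ceiling(0.5 * 200) = 100 -> 500 ms
  expect_equal(compute_ssrt_integration(401:600, 0, 0.5, 250), 250)
  # omissions are appended as the maximum observed go RT: with 2 omissions the
  # distribution becomes {400, 500, 600, 600, 600}; rank ceiling(.6*5)=3 -> 600
  expect_equal(compute_ssrt_integration(c(400, 500, 600), 2, 0.6, 100), 500)
  expect_error(compute_ssrt_integration(numeric(0), 0, 0.5, 100))
  expect_error(compute_ssrt_integration(500, 0, 1, 100))
  expect_error(compute_ssrt_integration(500, 0, 0, 100))
})

test_that("integration SSRT recovers the generative SSRT from full sessions", {
  cfg <- design_config(n_blocks = 8, seed = 1)  # 120 stop trials per modality
  est <- unlist(lapply(1:8, function(i) {
    cfg$seed <- i
    summarize_behavior(simulate_participant(cfg))$ssrt
  }))
  expect_lt(abs(median(est) - 220), 20)
})

test_that("behavioral summaries reproduce a hand-built toy table", {
  ev <- tibble::tibble(
    trial = 1:8,
    modality = "manual",
    trial_type = c("go", "go", "go", "go", "stop", "stop", "stop", "stop"),
    ssd_ms = c(NA, NA, NA, NA, 200, 250, 200, 250),
    rt_ms = c(400, 500, 600, 700, 350, 450, NA, NA),
    outcome = c(rep("go-correct", 4), "stop-fail", "stop-fail",
                "stop-success", "stop-success")
  )
  b <- summarize_behavior(ev)
  expect_equal(b$mean_go_rt, 550)
  expect_equal(b$mean_failed_stop_rt, 400)
  expect_equal(b$p_inhibit, 0.5)
  expect_equal(b$mean_ssd, 225)
  expect_equal(b$omission_rate, 0)
  # SSRT by hand: rank ceiling(.5*4) = 2 -> 500; 500 - 225 = 275
  expect_equal(b$ssrt, 275)
})

test_that("degenerate stopping patterns are flagged rather than silently summarized", {
  ev <- tibble::tibble(
    trial = 1:4, modality = "vocal",
    trial_type = c("go", "go", "stop", "stop"),
    ssd_ms = c(NA, NA, 300, 300),
    rt_ms = c(500, 520, NA, NA),
    outcome = c("go-correct", "go-correct", "stop-success", "stop-success")
  )
  b <- summarize_behavior(ev)
  expect_equal(b$p_inhibit, 1)
  expect_true(is.nan(b$mean_failed_stop_rt))
  expect_true(is.na(b$ssrt))
  expect_error(summarize_behavior(ev[ev$trial_type == "go", ]))
})

test_that("summary counts are conserved against the raw events", {
  ev <- simulate_participant(tiny_design(seed = 17))
  b <- summarize_behavior(ev)
  expect_equal(sum(b$n_trials), nrow(ev))
  expect_equal(sum(b$n_go) + sum(b$n_stop), nrow(ev))
})
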