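test_that("Cohen's d follows the pooled-SD formula", {
  # constructed so the pooled SD is exactly 0.4 and the mean gap 0.4 -> d = 1
  x <- 1.2 + c(-0.2, 0.2) * sqrt(2)
  y <- 0.8 + c(-0.2, 0.2) * sqrt(2)
  expect_equal(cohens_d(x, y), 1)
  # identical distributions give zero
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # antisymmetry
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20, 0.5)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  # agrees with a direct transcription of the formula
  sp <- sqrt((19 * var(a) + 19 * var(b)) / 38)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  expect_error(cohens_d(1, c(1, 2)))
  expect_error(cohens_d(c(1, 1), c(1, 1)))
})

test_that("the selective adjustment subtracts elementwise on aligned grids", {
  expect_equal(selective_adjustment(1.0, 0.4), 0.6)
  expect_equal(selective_adjustment(c(1, 1), c(1, 1)), c(0, 0))
  expect_equal(selective_adjustment(c(0.3, 0.5), c(0, 0)), c(0.3, 0.5))
  expect_error(selective_adjustment(c(1, 2), c(1, 2, 3)))
})

test_that("category assignment matches the worked cases", {
  expect_equal(classify_participant(c(.5, .5, .5), c(0, .3, .6)),
               "global-then-selective")
  expect_equal(classify_participant(c(0, 0, .1), c(0, 0, .1)), "neither")
  expect_equal(classify_participant(c(.3, .3, .3), c(.1, .1, .1)),
               "global-only")
  expect_equal(classify_participant(c(.1, .1, .1), c(.3, .3, .3)),
               "selective-only")
  expect_equal(classify_participant(c(.5, .5, .5), c(.5, .5, .5)),
               "same-time")
  expect_equal(classify_participant(c(0, .6, .6), c(.6, .6, .6)),
               "selective-then-global")
  # two timepoints work under the same rules, no special casing
  expect_equal(classify_participant(c(.5, .5), c(0, .6)),
               "global-then-selective")
  expect_error(classify_participant(c(.5), c(.5)))
  expect_error(classify_participant(c(NA, 1, 1), c(0, 0, 0)))
})

test_that("implementation and brute-force enactment agree on the full grid", {
  vals <- c(0, .1, .3, .5)
  grid <- as.matrix(expand.grid(vals, vals, vals))
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      g <- grid[i, ]; s <- grid[j, ]
      expect_identical(classify_participant(g, s), brute_force_classify(g, s),
                       label = paste("g =", paste(g, collapse = ","),
                                     "s =", paste(s, collapse = ",")))
    }
  }
})

test_that("classification is total and threshold-monotone", {
  set.seed(42)
  for (i in 1:300) {
    g <- round(rnorm(3, 0.2, 0.4), 2)
    s <- round(rnorm(3, 0.2, 0.4), 2)
    lo <- classify_participant(g, s, threshold = 0.2)
    hi <- classify_participant(g, s, threshold = 0.4)
    expect_true(lo %in% c("global-then-selective", "selective-then-global",
                          "same-time", "global-only", "selective-only",
                          "neither"))
    # raising the threshold never turns "neither" into a shown category
    if (lo == "neither") expect_equal(hi, "neither")
  }
})

test_that("the pairwise-increase convention is available and differs where it should", {
  # running-max: increases relative to the best earlier level
  g <- c(.5, .1, .45)   # running-max increases: .5, -.4, -.05
  s <- c(.1, .1, .5)
  expect_equal(classify_participant(g, s, increase = "running-max"),
               "global-then-selective")
  # a profile that dips and recovers flips the winning timepoint between
  # conventions: running-max increases (.25, -.04, .25) tie at t1/t3 -> t1;
  # pairwise increases (.25, -.04, .29) -> t3
  g2 <- c(.25, .21, .5)
  s2 <- c(.5, .5, .5)    # winner t1 under both conventions
  expect_equal(classify_participant(g2, s2, increase = "running-max"),
               "same-time")
  expect_equal(classify_participant(g2, s2, increase = "pairwise"),
               "selective-then-global")
})

test_that("category tabulation lists every category with conserved counts", {
  profs <- tibble::tibble(
    participant = c("a", "b", "c", "d"),
    category = c("global-then-selective", "global-then-selective",
                 "selective-only", "neither")
  )
  tab <- tabulate_categories(profs)
  expect_equal(nrow(tab), 6)
  expect_equal(sum(tab$n), 4)
  expect_equal(tab$pct[tab$category == "global-then-selective"], 50)
  expect_equal(tab$n[tab$category == "same-time"], 0)
  expect_equal(sum(tab$pct), 100)
  expect_error(tabulate_categories(profs[0, ]))
})

test_that("profiles computed from a session have the expected shape", {
  s <- sim_session(config = design_config(n_blocks = 4, trials_per_block = 45,
                                          seed = 19), seed = 6)
  pr <- compute_effect_profiles(s$measurements, s$events)
  expect_equal(nrow(pr), 3)
  expect_equal(pr$stim_time_ms, c(150, 200, 250))
  expect_true(all(is.finite(pr$nonselective_d)))
  expect_true(all(is.finite(pr$selective_d)))
  cats <- classify_profiles(pr)
  expect_equal(nrow(cats), 1)
})
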