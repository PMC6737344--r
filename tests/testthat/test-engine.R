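test_that("baseline normalisation subtracts the preceding block mean", {
  expect_equal(normalize_volume(5, c(5, 5, 5)), 0)
  expect_equal(normalize_volume(4, c(1, 2, 3)), 2)
  expect_equal(normalize_volume(rep(3, 10), rep(3, 5)), rep(0, 10))
  expect_error(normalize_volume(1, numeric(0)), "preceding subtraction")
})

test_that("window correlation matches the Pearson formula and handles degeneracy", {
  x <- 1:10
  expect_equal(as.numeric(window_correlation(x, x)), 1)
  expect_equal(as.numeric(window_correlation(x, -x)), -1)
  y <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
  expect_equal(as.numeric(window_correlation(x, y)), brute_pearson(x, y),
               tolerance = 1e-14)
  # random windows against base cor()
  set.seed(9)
  for (i in 1:25) {
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(as.numeric(window_correlation(a, b)), cor(a, b),
                 tolerance = 1e-12)
  }
  z <- window_correlation(rep(1, 10), rnorm(10))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  expect_error(window_correlation(1:3, 1:4))
})

test_that("sigmoid weighting is a monotone logistic with midpoint 0.5", {
  cfg <- engine_config()
  expect_equal(sigmoid_weight(cfg$sigmoid_midpoint, cfg), 0.5)
  expect_gt(sigmoid_weight(1, cfg), 0.99)
  set.seed(2)
  r1 <- runif(200, -1, 1); r2 <- runif(200, -1, 1)
  lo <- pmin(r1, r2); hi <- pmax(r1, r2)
  keep <- lo < hi
  expect_true(all(sigmoid_weight(lo[keep], cfg) <
                    sigmoid_weight(hi[keep], cfg)))
  # level mapping spans [0, 100] over the analytic range
  expect_equal(level_from_score(sigmoid_weight(-1, cfg), cfg), 0)
  expect_equal(level_from_score(sigmoid_weight(1, cfg), cfg), 100)
})

test_that("motion gating thresholds translation and rotation RMS separately", {
  cfg <- engine_config()
  g0 <- motion_gate(rep(0, 6), cfg)
  expect_true(g0$include); expect_false(g0$warning)

  # RMS of (3,0,0) = sqrt(3) > 1 mm -> excluded with warning
  g1 <- motion_gate(c(3, 0, 0, 0, 0, 0), cfg)
  expect_false(g1$include); expect_true(g1$warning)
  expect_equal(g1$rms_translation, sqrt(3))

  # exactly at threshold: excluded (inclusion is strict)
  g2 <- motion_gate(c(0, 0, 0, 1, 1, 1), cfg)
  expect_equal(g2$rms_rotation, 1)
  expect_false(g2$include)

  expect_error(motion_gate(c(1, 2, 3), cfg), "6 finite values")
})

test_that("warm-up keeps the neutral level and emits no correlation", {
  cfg <- engine_config()
  st <- new_feedback_state(cfg)
  for (i in 1:9) {
    res <- feedback_step(st, rnorm(1), rnorm(1), "GUILT", "INCREASE")
    st <- res$state
    expect_equal(res$level, 50)
    expect_true(is.na(res$r))
  }
  res <- feedback_step(st, rnorm(1), rnorm(1), "GUILT", "INCREASE")
  expect_false(is.na(res$r))
  expect_error(feedback_step(st, 0, 0, "SUBTRACTION", "INCREASE"),
               "SUBTRACTION")
})

test_that("reinforcement rules move the level in the documented direction", {
  cfg <- engine_config()
  st <- new_feedback_state(cfg)
  # seed a history with known statistics: mean 0.2, some spread
  st$history$GUILT <- c(0.1, 0.2, 0.3, 0.2, 0.2)
  hist <- st$history$GUILT
  wm <- sum(seq_along(hist) * hist) / sum(seq_along(hist))
  s <- sd(hist)
  st$current_level <- 50

  # fill buffers with a strongly correlated window: r = 1 > wm + s -> up
  st$atl_buffer <- 1:10; st$scc_buffer <- 1:10
  res <- feedback_step(st, 11, 11, "GUILT", "INCREASE")
  expect_equal(res$level, 60)
  expect_gt(res$r, wm + s)

  # anti-correlated window: r = -1, outside wm +/- s -> STABILISE down
  st$atl_buffer <- 1:10; st$scc_buffer <- -(1:10)
  res <- feedback_step(st, 11, -11, "GUILT", "STABILISE")
  expect_equal(res$level, 40)

  # with history (.8, -.8, .8, -.8): wm = -0.16, sd = 0.924, so r = -1
  # lies inside the band (|r - wm| = 0.84) while r = 1 lies outside (1.16)
  st2 <- new_feedback_state(cfg)
  st2$history$GUILT <- c(0.8, -0.8, 0.8, -0.8)
  st2$current_level <- 50
  st2$atl_buffer <- 1:10; st2$scc_buffer <- -(1:10)
  res2 <- feedback_step(st2, 11, -11, "GUILT", "STABILISE")
  expect_equal(res2$r, -1)
  expect_equal(res2$level, 60)
  st2$atl_buffer <- 1:10; st2$scc_buffer <- 1:10
  res3 <- feedback_step(st2, 11, 11, "GUILT", "STABILISE")
  expect_equal(res3$level, 40)
})

test_that("replayed window correlations equal brute-force Pearson on retained samples", {
  cfg <- engine_config()
  tl <- build_neurofeedback_run()
  set.seed(21)
  for (rep_i in 1:2) {
    atl <- rnorm(360); scc <- rnorm(360)
    motion <- matrix(rnorm(360 * 6, sd = 0.4), ncol = 6)  # some gating
    tr <- engine_replay(atl, scc, tl, "INCREASE", motion = motion,
                        config = cfg)
    exp_r <- expected_window_r(atl, scc, tl, motion, cfg)
    got <- tr[!is.na(tr$r), c("volume", "r")]
    expect_equal(got$volume, exp_r$volume)
    expect_equal(got$r, exp_r$r, tolerance = 1e-12)
  }
})

test_that("the level sequence is bounded, deterministic, and resets with blocks", {
  cfg <- engine_config()
  set.seed(33)
  s <- generate_subject(include_nf = TRUE, seed = 14)
  tr1 <- run_feedback_session(s, "ACTIVE", cfg)
  tr2 <- run_feedback_session(s, "ACTIVE", cfg)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  expect_true(all(tr1$level >= 0 & tr1$level <= 100))
  # warm-up rows (first window_volumes retained of each block) stay neutral
  warm <- is.na(tr1$r) & !tr1$gated
  expect_true(all(tr1$level[warm] == 50))
})

test_that("gated volumes are excluded from buffers and counted", {
  cfg <- engine_config()
  tl <- build_neurofeedback_run()
  set.seed(44)
  atl <- rnorm(360); scc <- rnorm(360)
  motion <- matrix(0, 360, 6)
  bad <- c(113, 114, 121)   # 0-based 112,113,120: retained guilt volumes
  motion[bad, 1] <- 5
  tr <- engine_replay(atl, scc, tl, "INCREASE", motion = motion,
                      config = cfg)
  gated_rows <- tr[tr$gated, ]
  expect_equal(nrow(gated_rows), 3L)
  expect_equal(gated_rows$volume, c(112, 113, 120))
  expect_equal(attr(tr, "gated_count"), sum(tr$gated))
  expect_true(all(is.na(gated_rows$r)))
  # correlations after gating still match the brute-force stream oracle
  exp_r <- expected_window_r(atl, scc, tl, motion, cfg)
  expect_equal(tr$r[!is.na(tr$r)], exp_r$r, tolerance = 1e-12)
  # no-motion replay has zero gated volumes
  tr0 <- engine_replay(atl, scc, tl, "INCREASE", config = cfg)
  expect_equal(attr(tr0, "gated_count"), 0L)
})

test_that("session rules follow the arm: control stabilises everything", {
  s <- generate_subject(include_nf = TRUE, seed = 5)
  trC <- run_feedback_session(s, "CONTROL")
  expect_true(all(trC$rule == "STABILISE"))
  trA <- run_feedback_session(s, "ACTIVE")
  expect_true(all(trA$rule[trA$condition == "GUILT"] == "INCREASE"))
  expect_true(all(trA$rule[trA$condition == "INDIGNATION"] == "STABILISE"))
  # per-condition average equals a brute-force filter-and-average
  cm <- attr(trA, "condition_means")
  ok <- !trA$gated
  expect_equal(cm[["GUILT"]],
               mean(trA$level[ok & trA$condition == "GUILT"]))
  expect_equal(cm[["INDIGNATION"]],
               mean(trA$level[ok & trA$condition == "INDIGNATION"]))
})

test_that("stabilise feedback on a stationary process keeps the level high", {
  means <- sapply(1:6, function(i) {
    s <- generate_subject(coupling_spec(0.3, 0.3, 0.3, 0.3), "CONTROL",
                          motion_spike_prob = 0, include_nf = TRUE,
                          seed = 200 + i)
    tr <- run_feedback_session(s, "CONTROL")
    attr(tr, "condition_means")[["GUILT"]]
  })
  expect_gt(mean(means), 50)
})

test_that("increase is harder than stabilisation on identical data", {
  # same series replayed under both rules: guilt levels lower under INCREASE
  diffs <- sapply(1:10, function(i) {
    s <- generate_subject(coupling_spec(0.3, 0.4, 0.3, 0.4),
                          motion_spike_prob = 0, include_nf = TRUE,
                          seed = 300 + i)
    a <- attr(run_feedback_session(s, "ACTIVE"), "condition_means")[["GUILT"]]
    c_ <- attr(run_feedback_session(s, "CONTROL"), "condition_means")[["GUILT"]]
    a - c_
  })
  expect_lt(binom.test(sum(diffs < 0), length(diffs),
                       alternative = "greater")$p.value, 0.05)
})

test_that("traces round-trip through the TSV dialect", {
  s <- generate_subject(include_nf = TRUE, seed = 8)
  tr <- run_feedback_session(s)
  p <- file.path(tempdir(), "trace.tsv")
  write_trace_tsv(tr, p)
  back <- read_trace_tsv(p)
  expect_equal(back$level, tr$level)
  expect_equal(back$condition, tr$condition)
  expect_equal(names(back)[1:7],
               c("volume", "condition", "r", "score", "level", "gated", "rule"))
})
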