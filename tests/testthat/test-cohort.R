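test_that("zero-SD groups reproduce the group means exactly", {
  spec <- group_spec("g", 1, a_mean = 8.86, a_sd = 0, z_mean = 0.43,
                     z_sd = 0, v_mean = 8.48, v_sd = 0, t0_mean = 0.28,
                     t0_sd = 0, ssrt_mean = 300, ssrt_sd = 0)
  s <- draw_subject(spec, seed = 1)
  expect_equal(s$params$a, 8.86)
  expect_equal(s$params$z, 0.43)
  expect_equal(s$params$v, 8.48)
  expect_equal(s$params$t0, 0.28)
})

test_that("subject draws respect domains and truncated-normal moments", {
  spec <- small_specs()[[1]]
  draws <- replicate(5000, {
    s <- draw_subject(spec)
    c(s$params$a, s$params$z, s$params$v, s$params$t0)
  })
  expect_true(all(draws[1, ] > 0))
  expect_true(all(draws[2, ] > 0 & draws[2, ] < 1))
  expect_true(all(draws[3, ] > 0))
  expect_true(all(draws[4, ] >= 0))
  m_z <- etruncnorm(spec$z_mean, spec$z_sd, 0, 1)
  expect_lt(abs(mean(draws[2, ]) - m_z), 3 * spec$z_sd / sqrt(5000))
})

test_that("means far outside the domain raise a configuration error", {
  spec <- group_spec("bad", 1, a_mean = 8.86, a_sd = 0.2, z_mean = 0.43,
                     z_sd = 0.1, v_mean = 8.48, v_sd = 0.2,
                     t0_mean = 0.28, t0_sd = 0.02,
                     ssrt_mean = 300, ssrt_sd = 50)
  spec$t0_mean <- -10   # pathological, bypassing the constructor
  expect_error(draw_subject(spec, seed = 1), "1e-6")
})

test_that("the race rule decides stop trials by the printed inequality", {
  s <- degenerate_subject(rt_go_ms = 900, ssrt_ms = 300)
  set.seed(1)
  # inhibit iff rt_go > ssd + ssrt: 900 > 590 + 300 -> signal-stop
  tr <- simulate_stop_trial(s, ssd = 590)
  expect_equal(tr$outcome, "signal-stop")
  expect_false(tr$responded)
  expect_true(is.na(tr$rt_ms))
  # 900 > 650 + 300 is false -> signal-respond at the go RT
  tr <- simulate_stop_trial(s, ssd = 650)
  expect_equal(tr$outcome, "signal-respond")
  expect_equal(tr$rt_ms, 900, tolerance = 1)
})

test_that("stop-trial response rate matches the race-model convolution", {
  spec <- small_specs()[[1]]
  s <- draw_subject(spec, seed = 4)
  ssd <- 550
  set.seed(8)
  resp <- replicate(2e4, simulate_stop_trial(s, ssd)$responded)
  # P(respond) = E over SSRT of F_go(ssd + ssrt), by numerical integration
  p_num <- integrate(function(u)
    dtruncnorm(u, s$ssrt_mean, s$ssrt_sd, 0, Inf) *
      ddm_cdf((ssd + u) / 1000, s$params),
    0, s$ssrt_mean + 8 * s$ssrt_sd)$value
  expect_lt(abs(mean(resp) - p_num), 3.5 * sqrt(p_num * (1 - p_num) / 2e4))
})

test_that("sessions have the specified structure and staircase dynamics", {
  s <- draw_subject(small_specs()[[1]], seed = 2)
  cfg <- session_config(seed = 3)
  set.seed(3)
  ses <- simulate_session(s, cfg)
  expect_equal(nrow(ses), 200)
  expect_equal(sum(ses$type == "go"), 150)
  expect_equal(sum(ses$type == "stop"), 50)
  expect_equal(sum(ses$type == "stop" & ses$block == 1), 10)
  # staircase: +step after signal-stop, -step after signal-respond,
  # carried across the whole session
  st <- ses[ses$type == "stop", ]
  expected_step <- ifelse(st$outcome == "signal-stop", 30, -30)
  next_ssd <- pmin(pmax(st$ssd_ms + expected_step, 30), 2400)
  expect_equal(st$ssd_ms[-1], next_ssd[-nrow(st)])
  # zero step freezes the SSD
  cfg0 <- session_config(staircase_step = 0, seed = 3)
  set.seed(3)
  ses0 <- simulate_session(s, cfg0)
  expect_true(all(ses0$ssd_ms[ses0$type == "stop"] == 500))
})

test_that("cohorts are sized, labelled, and seed-reproducible", {
  specs <- small_specs(n = 15)
  tab1 <- simulate_cohort(specs, session_config(seed = 42))
  tab2 <- simulate_cohort(specs, session_config(seed = 42))
  expect_equal(nrow(tab1), 30 * 200)
  expect_identical(tab1, tab2)
  expect_equal(length(unique(tab1$subject)), 30)
  expect_setequal(unique(tab1$group), c("SZ", "control"))
  dup <- list(specs[[1]], specs[[1]])
  expect_error(simulate_cohort(dup, session_config(seed = 1)), "duplicate")
  # group mean go RT ordered as the closed-form mean predicts
  # (higher z -> shorter RT)
  m <- tapply(tab1$rt_ms[tab1$type == "go"], tab1$group[tab1$type == "go"],
              mean)
  expect_lt(m[["SZ"]], m[["control"]])
})

test_that("the 1-up/1-down staircase converges on 50% responding", {
  s <- draw_subject(small_specs()[[2]], seed = 5)
  run <- staircase_run(s, 8000, seed = 6)
  prop <- mean(run$responded[-(1:500)])
  expect_lt(abs(prop - 0.5), 0.02)
  expect_true(all(run$ssd_ms >= 30 & run$ssd_ms <= 2400))
})

test_that("signal-respond RTs are the fast tail of the go distribution", {
  # context independence by construction: truncation above at ssd + ssrt
  flags <- vapply(1:25, function(r) {
    s <- draw_subject(small_specs()[[1]], seed = 100 + r)
    set.seed(200 + r)
    ses <- simulate_session(s, session_config(seed = 200 + r))
    chk <- suppressWarnings(context_independence_check(ses))
    isTRUE(chk$signal_respond_faster)
  }, logical(1))
  expect_gte(mean(flags), 0.95)
})

test_that("trial tables round-trip through TSV and validate cleanly", {
  tab <- simulate_cohort(small_specs(n = 2),
                         session_config(n_blocks = 2, seed = 9))
  path <- tempfile(fileext = ".tsv")
  write_trial_table(tab, path)
  back <- read_trial_table(path)
  expect_equal(back$rt_ms, tab$rt_ms, tolerance = 1e-9)
  expect_identical(back$outcome, tab$outcome)
  val <- validate_trial_table(back)
  expect_true(attr(val, "valid"))
  # planted violations are flagged
  bad <- back
  bad$ssd_ms[bad$type == "stop"][1] <- -10
  expect_gt(sum(validate_trial_table(bad)$violations), 0)
  bad2 <- back
  bad2$rt_ms[bad2$responded][1] <- NA
  expect_gt(sum(validate_trial_table(bad2)$violations), 0)
})
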