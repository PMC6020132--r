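test_that("temporal estimation error follows the printed definition", {
  tee <- compute_tee(c(898.84, 1000, 1100), collision_time = 1000)
  expect_equal(tee$tee, c(-101.16, 0, 100))
  # the boundary is inclusive: a response exactly at the collision is early
  expect_equal(tee$sign, c("early", "early", "late"))
})

test_that("exclusion drops only out-of-window go trials, strictly", {
  tt <- toy_trials()
  tt$rt_ms[tt$type == "go"] <- c(1300, -5, 1250)
  out <- exclusion_filter(tt)
  kept <- out$rt_ms[out$type == "go"]
  expect_equal(kept, 1250)              # 1300 and -5 dropped, 1250 retained
  expect_equal(nrow(out[out$type == "stop", ]),
               nrow(tt[tt$type == "stop", ]))
  log <- attr(out, "exclusion_log")
  expect_equal(log$n_slow, 1)
  expect_equal(log$n_fast, 1)
  expect_equal(log$prop_slow, 1 / 3)
  # idempotent and non-mutating (the second pass logs zero exclusions)
  out2 <- exclusion_filter(out)
  attr(out, "exclusion_log") <- NULL
  attr(out2, "exclusion_log") <- NULL
  expect_equal(out2, out)
  expect_equal(nrow(out2), nrow(out))
  expect_equal(tt$rt_ms[tt$type == "go"], c(1300, -5, 1250))
})

test_that("summary-statistic t tests reproduce the published statistics", {
  # impulsiveness scores, Welch
  w <- two_sample_t(66.53, 4.07, 15, 50.60, 8.52, 15, "welch")
  expect_equal(abs(w$statistic), 6.53, tolerance = 5e-3)
  expect_equal(w$df, 20.07, tolerance = 5e-3)
  # anxiety scores, pooled
  p <- two_sample_t(12.07, 2.19, 15, 4.07, 3.17, 15, "pooled")
  expect_equal(abs(p$statistic), 8.04, tolerance = 5e-3)
  expect_equal(p$df, 28)
  # identical summaries give t = 0
  expect_equal(two_sample_t(5, 1, 10, 5, 1, 10)$statistic, 0)
  expect_error(two_sample_t(5, 0, 10, 6, 0, 10), "zero variance")
  expect_equal(two_sample_t(5, 0, 10, 5, 0, 10)$statistic, 0)
})

test_that("summary-statistic t agrees with t.test on matching raw data", {
  # construct raw samples with exactly the target moments
  exact <- function(m, s, n) {
    x <- scale(rnorm(n))            # mean 0, sd 1 exactly
    as.vector(x) * s + m
  }
  set.seed(14)
  x <- exact(66.53, 4.07, 15); y <- exact(50.60, 8.52, 15)
  w <- two_sample_t(66.53, 4.07, 15, 50.60, 8.52, 15, "welch")
  tt <- t.test(x, y)
  expect_equal(w$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
  tp <- t.test(x, y, var.equal = TRUE)
  p <- two_sample_t(66.53, 4.07, 15, 50.60, 8.52, 15, "pooled")
  expect_equal(p$statistic, unname(tp$statistic), tolerance = 1e-10)
})

test_that("Welch df never exceeds the pooled df", {
  set.seed(15)
  for (i in 1:20) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    w <- two_sample_t(rnorm(1), runif(1, 0.5, 3), n1,
                      rnorm(1), runif(1, 0.5, 3), n2, "welch")
    expect_lte(w$df, n1 + n2 - 2 + 1e-12)
  }
  eq <- two_sample_t(1, 2, 12, 3, 2, 12, "welch")
  expect_equal(eq$df, 22)               # equal variances and n: equality
})

test_that("paired subject-mean comparison has df = n - 1", {
  set.seed(16)
  x <- rnorm(15, 1000, 30); y <- x - rnorm(15, 40, 10)
  pt <- paired_t(x, y)
  expect_equal(pt$df, 14)
  d <- x - y
  expect_equal(pt$statistic, mean(d) / (sd(d) / sqrt(15)),
               tolerance = 1e-12)
})

test_that("group summaries match a brute-force recomputation", {
  tab <- simulate_cohort(small_specs(n = 5),
                         session_config(n_blocks = 2, seed = 55))
  f <- exclusion_filter(tab)
  gs <- group_summary(f, collision_time = 1000)
  # brute force for one group and two measures
  sz <- f[f$group == "SZ", ]
  go_rt <- sz$rt_ms[sz$type == "go" & sz$responded]
  expect_equal(gs$mean[gs$group == "SZ" & gs$measure == "rt_go_ms"],
               mean(go_rt), tolerance = 1e-9)
  expect_equal(gs$mean[gs$group == "SZ" & gs$measure == "abs_tee_ms"],
               mean(abs(go_rt - 1000)), tolerance = 1e-9)
  # subject-level SSRT aggregation
  rs <- race_summary(sz, filter = FALSE)
  expect_equal(gs$mean[gs$group == "SZ" & gs$measure == "ssrt_ms"],
               mean(rs$ssrt), tolerance = 1e-9)
  # inhibition accuracy is reported in percent over trials
  st <- sz$outcome[sz$type == "stop"]
  expect_equal(gs$mean[gs$group == "SZ" &
                         gs$measure == "inhibition_accuracy_pct"],
               100 * mean(st == "signal-stop"), tolerance = 1e-9)
})

test_that("degenerate identical subjects give zero-SD summaries", {
  spec <- group_spec("g", 3, a_mean = 8.86, a_sd = 0, z_mean = 0.43,
                     z_sd = 0, v_mean = 8.48, v_sd = 0, t0_mean = 0.28,
                     t0_sd = 0, ssrt_mean = 300, ssrt_sd = 0)
  tab <- simulate_cohort(list(spec), session_config(n_blocks = 1, seed = 2))
  gs <- group_summary(exclusion_filter(tab))
  s50 <- gs[gs$measure == "ssd50_ms", ]
  # subjects share parameters but see independent trials; subject-level
  # SSD50s still differ, only the degenerate stop process is exact
  expect_equal(nrow(s50), 1)
  expect_true(is.finite(s50$mean))
})
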