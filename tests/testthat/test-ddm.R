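test_that("parameter constructor enforces the domain", {
  expect_s3_class(ddm_params(1, 0.5, 1, 0), "ddm_params")
  expect_error(ddm_params(-1, 0.5, 1, 0.1), "'a'")
  expect_error(ddm_params(1, 0, 1, 0.1), "'z'")
  expect_error(ddm_params(1, 1, 1, 0.1), "'z'")
  expect_error(ddm_params(1, 0.5, 0, 0.1), "'v'")
  expect_error(ddm_params(1, 0.5, 1, -0.1), "'t0'")
  expect_error(ddm_params(Inf, 0.5, 1, 0.1), "'a'")
})

test_that("density vanishes at and below the non-decision time", {
  p <- table1_params()
  expect_equal(ddm_density(p$t0, p), 0)
  expect_equal(ddm_density(p$t0 - 0.1, p), 0)
  expect_gt(ddm_density(p$t0 + 0.05, p), 0)
  expect_identical(ddm_density(p$t0, p, log = TRUE), -Inf)
})

test_that("density integrates to one for random parameter sets", {
  set.seed(42)
  for (i in 1:10) {
    p <- ddm_params(a = runif(1, 1, 15), z = runif(1, 0.05, 0.95),
                    v = runif(1, 1, 15), t0 = runif(1, 0, 0.5))
    mu <- p$a * (1 - p$z) / p$v
    val <- integrate(ddm_density, p$t0, p$t0 + 30 * mu, params = p,
                     rel.tol = 1e-9)$value
    expect_equal(val, 1, tolerance = 1e-6)
  }
})

test_that("density matches a finite difference of the empirical CDF", {
  p <- table1_params()
  x <- ddm_sample(p, 1e6, seed = 7)
  for (q in c(0.78, 0.9, 1.05)) {
    h <- 0.01
    emp <- (mean(x <= q + h) - mean(x <= q - h)) / (2 * h)
    # Monte-Carlo error of the difference quotient plus a small
    # discretization allowance
    se <- sqrt(ddm_density(q, p) * 2 * h / 1e6) / (2 * h)
    expect_lt(abs(ddm_density(q, p) - emp), 4 * se + 0.005)
  }
})

test_that("log-likelihood is a stable sum of log densities", {
  p <- table1_params()
  rt <- ddm_sample(p, 100, seed = 3)
  expect_equal(ddm_loglik(rt, p), sum(log(ddm_density(rt, p))),
               tolerance = 1e-10)
  expect_equal(ddm_loglik(rt[1], p), log(ddm_density(rt[1], p)))
  expect_identical(ddm_loglik(c(rt, p$t0 - 0.01), p), -Inf)
  expect_identical(ddm_loglik(c(rt, p$t0), p), -Inf)
  expect_equal(ddm_loglik(numeric(0), p), 0)
  expect_error(ddm_loglik(c(1, NA), p), "finite")
})

test_that("sampler agrees with the analytic CDF and closed-form moments", {
  p <- table1_params()
  n <- 1e5
  x <- ddm_sample(p, n, seed = 11)
  expect_true(all(x > p$t0))
  # Kolmogorov-Smirnov distance against the analytic CDF
  xs <- sort(x)
  ks <- max(abs(seq_len(n) / n - ddm_cdf(xs, p)))
  expect_lt(ks, 0.01)
  # moments within 3 standard errors
  m_th <- mean_rt(p)                    # 0.28 + 8.86 * 0.57 / 8.48
  v_th <- var_rt(p)
  expect_equal(m_th, 0.28 + 8.86 * (1 - 0.43) / 8.48)
  se_mean <- sqrt(v_th / n)
  expect_lt(abs(mean(x) - m_th), 3 * se_mean)
  m4 <- mean((x - mean(x))^4)
  se_var <- sqrt((m4 - v_th^2) / n)
  expect_lt(abs(var(x) - v_th), 3 * se_var)
})

test_that("sampling is reproducible given a seed and leaves the RNG alone", {
  p <- table1_params()
  set.seed(123)
  before <- .Random.seed
  x1 <- ddm_sample(p, 50, seed = 9)
  expect_identical(before, .Random.seed)
  x2 <- ddm_sample(p, 50, seed = 9)
  expect_identical(x1, x2)
})

test_that("mean RT has the analytic limits and monotonicities", {
  p <- table1_params()
  # z -> 1: no remaining distance, mean -> t0
  expect_equal(mean_rt(ddm_params(8.86, 1 - 1e-9, 8.48, 0.28)), 0.28,
               tolerance = 1e-8)
  # doubling a and v together leaves the mean unchanged
  expect_equal(mean_rt(ddm_params(2 * 8.86, 0.43, 2 * 8.48, 0.28)),
               mean_rt(p))
  base <- mean_rt(p)
  expect_lt(mean_rt(ddm_params(8.86, 0.43, 9.48, 0.28)), base)  # v up
  expect_lt(mean_rt(ddm_params(8.86, 0.53, 8.48, 0.28)), base)  # z up
  expect_gt(mean_rt(ddm_params(9.86, 0.43, 8.48, 0.28)), base)  # a up
  expect_gt(mean_rt(ddm_params(8.86, 0.43, 8.48, 0.38)), base)  # t0 up
})

test_that("closed-form mean agrees with Monte-Carlo for random parameters", {
  set.seed(5)
  for (i in 1:5) {
    p <- ddm_params(a = runif(1, 2, 12), z = runif(1, 0.2, 0.8),
                    v = runif(1, 2, 12), t0 = runif(1, 0, 0.4))
    x <- ddm_sample(p, 5e4)
    expect_lt(abs(mean(x) - mean_rt(p)), 4 * sqrt(var_rt(p) / 5e4))
  }
})
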