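# Cronbach's alpha, rater differences, paired t, and sample size.

test_that("alpha is exactly 1 for identical non-constant series", {
  expect_identical(cronbach_alpha(1:10, 1:10), 1)
  expect_identical(cronbach_alpha(c(2.2, 5.1, 3.3, 9), c(2.2, 5.1, 3.3, 9)), 1)
})

test_that("alpha is 0 when the sample covariance is exactly 0", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 4, 3)   # cov(x, y) = 0.5 -- construct a zero-cov pair instead
  y <- y - cov(x, y) / var(x) * x   # residualize: cov becomes exactly 0
  expect_equal(cov(x, y), 0, tolerance = 1e-15)
  expect_equal(cronbach_alpha(x, y), 0, tolerance = 1e-12)
})

test_that("alpha matches the direct two-item variance formula", {
  x <- c(1, 2, 3, 4); y <- c(1.1, 2.0, 2.9, 4.2)
  oracle <- (2 / 1) * (1 - (var(x) + var(y)) / var(x + y))
  expect_equal(cronbach_alpha(x, y), oracle, tolerance = 1e-15)
  # frozen hand computation: 2 * (1 - (5/3 + 5.25/3) / (20.45/3))
  expect_equal(cronbach_alpha(x, y), 20.4 / 20.45, tolerance = 1e-12)
})

test_that("alpha is invariant under common affine rescaling", {
  set.seed(21)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.3)
  a0 <- cronbach_alpha(x, y)
  expect_equal(cronbach_alpha(5 * x - 2, 5 * y - 2), a0, tolerance = 1e-12)
  expect_lte(a0, 1)
})

test_that("constant measurements are rejected as degenerate", {
  expect_error(cronbach_alpha(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("rater differences: zeros, constant shifts, and symmetry", {
  s <- expand.grid(subject = 1:6, landmark = c("Pn", "LLP"),
                   stringsAsFactors = FALSE)
  set.seed(2)
  s$x <- rnorm(12); s$y <- rnorm(12); s$z <- rnorm(12)
  same <- rater_differences(s, s)
  expect_true(all(same$summary$mean == 0))
  expect_true(all(same$summary$sd == 0))
  shifted <- s
  shifted$x[shifted$landmark == "Pn"] <- s$x[s$landmark == "Pn"] + 0.3
  d <- rater_differences(s, shifted)
  pn_dx <- d$summary[d$summary$landmark == "Pn" & d$summary$component == "dx", ]
  expect_equal(pn_dx$mean, 0.3, tolerance = 1e-12)
  expect_equal(pn_dx$sd, 0, tolerance = 1e-12)
  # symmetry
  d2 <- rater_differences(shifted, s)
  expect_equal(d$summary$mean, d2$summary$mean)
  # mismatched keys error lists the missing pair
  expect_error(rater_differences(s, s[-3, ]), "mismatched")
})

test_that("rater delta means follow the folded-normal expectation", {
  sigma <- 0.5
  truth <- data.frame(subject = 1:2000, landmark = "Pn",
                      x = 0, y = 0, z = 0)
  series <- generate_rater_series(rater_spec(truth, raters = c("A", "B"),
                                             sessions = 1, jitter_sd = sigma,
                                             seed = 77))
  a <- series[series$rater == "A", ]
  b <- series[series$rater == "B", ]
  d <- rater_differences(a, b)
  expected <- 2 * sigma / sqrt(pi)     # E|N(0, 2 sigma^2)|
  fold_sd <- sqrt(2 * sigma^2 * (1 - 2 / pi))
  for (comp in c("dx", "dy", "dz")) {
    m <- d$summary$mean[d$summary$component == comp]
    expect_lt(abs(m - expected), 3 * fold_sd / sqrt(2000))
  }
})

test_that("paired t handles the textbook cases and matches closed form", {
  r0 <- paired_t_test(c(2, 1, 4, 3), c(1, 2, 3, 4))   # diffs +1,-1,+1,-1
  expect_equal(r0$t, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)
  r1 <- paired_t_test(c(2, 2, 2, 2.0001), c(1, 1, 1, 1))
  expect_lt(r1$p_value, 0.001)
  set.seed(8)
  x <- rnorm(12); y <- rnorm(12, 0.4)
  r <- paired_t_test(x, y)
  d <- x - y
  t_oracle <- mean(d) / (sd(d) / sqrt(12))
  p_oracle <- 2 * pt(-abs(t_oracle), 11)
  expect_equal(r$t, t_oracle, tolerance = 1e-9)
  expect_equal(r$p_value, p_oracle, tolerance = 1e-9)
  expect_error(paired_t_test(c(1, 2, 3), c(0, 1, 2)), "degenerate")
})

test_that("the paired-t power function is monotone and the n minimal", {
  ns <- 2:60
  pw <- vapply(ns, paired_t_power, 0, effect_size = 0.5)
  expect_true(all(diff(pw) > 0))
  for (dz in c(0.4, 0.5, 0.8, 1.0)) {
    n <- required_sample_size_paired_t(dz, 0.05, 0.80)
    expect_gte(paired_t_power(n, dz), 0.80)
    expect_lt(paired_t_power(n - 1, dz), 0.80)
  }
})

test_that("sample size matches an independent exact-power implementation", {
  # oracle: stats::power.t.test (independent noncentral-t code path)
  for (dz in c(0.5, 1.0)) {
    scan <- vapply(2:100, function(n)
      power.t.test(n = n, delta = dz, sd = 1, sig.level = 0.05,
                   type = "paired")$power, 0)
    oracle_n <- (2:100)[which(scan >= 0.80)[1]]
    expect_identical(required_sample_size_paired_t(dz, 0.05, 0.80),
                     oracle_n)
  }
})

test_that("the reliability report reproduces the two-examiner battery", {
  truth <- data.frame(subject = rep(1:12, each = 2),
                      landmark = rep(c("Pn", "Co"), 12),
                      x = rnorm(24, 10), y = rnorm(24, -40), z = rnorm(24, 5))
  series <- generate_rater_series(rater_spec(truth, jitter_sd = 0,
                                             bias = 0, seed = 3))
  rep0 <- reliability_report(series)
  expect_true(all(rep0$intra$alpha == 1))
  expect_true(all(rep0$inter$alpha == 1))
  expect_true(all(rep0$differences$mean == 0))
  # with jitter, alphas stay below/at 1 and differences are positive
  series2 <- generate_rater_series(rater_spec(truth, jitter_sd = 0.2,
                                              seed = 4))
  rep2 <- reliability_report(series2)
  expect_true(all(rep2$intra$alpha <= 1))
  expect_true(all(rep2$differences$mean > 0))
})
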