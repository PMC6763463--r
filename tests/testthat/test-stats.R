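test_that("divergence scan requires all later timepoints to stay significant", {
  set.seed(20)
  a <- matrix(rnorm(6 * 8), 6)
  dv <- time_of_divergence(a, a, 1:8)
  expect_true(all(dv$p_values == 1))
  expect_false(dv$diverged)
  # a group separated from halfway on diverges exactly there
  times <- seq(0, 100, by = 10)
  b <- a2 <- matrix(rnorm(10 * 11, sd = 0.5), 10)
  b[, times >= 50] <- b[, times >= 50] - 8
  dv2 <- time_of_divergence(a2, b, times)
  expect_true(dv2$diverged)
  expect_equal(dv2$divergence_time_s, 50)
  # a single late non-significant timepoint voids earlier divergence
  b3 <- b; b3[, 11] <- a2[, 11]
  dv3 <- time_of_divergence(a2, b3, times)
  expect_false(dv3$diverged)
  expect_error(time_of_divergence(a, a[, 1:3], 1:8), "time grid")
})

test_that("divergence p-values agree with explicit rank-sum enumeration", {
  set.seed(21)
  for (rep in 1:20) {
    a <- matrix(runif(4 * 3), 4)   # combined n = 8 per timepoint, tie-free
    b <- matrix(runif(4 * 3), 4)
    dv <- time_of_divergence(a, b, 1:3)
    for (j in 1:3)
      expect_equal(dv$p_values[j], enum_wilcox_p(a[, j], b[, j]),
                   tolerance = 1e-12)
  }
})

test_that("simulated divergence is recovered and the null is calibrated", {
  hits <- vapply(1:25, function(sd) {
    sim <- simulate_group_traces(seed = sd)
    dv <- time_of_divergence(sim$a, sim$b, sim$times_s)
    dv$diverged && abs(dv$divergence_time_s - 50) <= 2.5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  fp <- vapply(1:60, function(sd) {
    sim <- simulate_group_traces(divergence_time_s = Inf,
                                 effect_size_sd = 0, seed = 1000 + sd)
    time_of_divergence(sim$a, sim$b, sim$times_s)$diverged
  }, logical(1))
  expect_lte(mean(fp), 0.10)
})

test_that("slope comparison via the interaction term behaves at the limits", {
  t <- seq(0, 10)
  a <- data.frame(t = t, y = 5 - 0.2 * t)
  expect_equal(compare_slopes(a, a)$p_value, 1)
  b <- data.frame(t = t, y = 5 - 0.1 * t)
  expect_lt(compare_slopes(a, b)$p_value, 1e-12)
  expect_equal(compare_slopes(a, b)$slope_difference, 0.1,
               tolerance = 1e-10)
  set.seed(22)
  an <- data.frame(t = t, y = 2 + 0.3 * t + rnorm(11, sd = 0.3))
  bn <- data.frame(t = t, y = 1 + 0.3 * t + rnorm(11, sd = 0.3))
  ref <- stats::lm(y ~ t * g,
                   data = rbind(cbind(an, g = 0), cbind(bn, g = 1)))
  expect_equal(compare_slopes(an, bn)$p_value,
               summary(ref)$coefficients["t:g", 4], tolerance = 1e-12)
  expect_error(compare_slopes(an[1:2, ], bn), ">= 3")
})

test_that("one-sample t against 100% matches the textbook formula", {
  r <- one_sample_t_norm100(c(100, 100, 100))
  expect_equal(r$t, 0); expect_equal(r$p_value, 1)
  r2 <- one_sample_t_norm100(c(90, 95, 100))
  expect_equal(r2$t, -sqrt(3), tolerance = 1e-9)
  expect_equal(r2$p_value, 2 * pt(-sqrt(3), 2), tolerance = 1e-12)
  expect_equal(round(r2$t, 3), -1.732)
  expect_equal(round(r2$p_value, 3), 0.225)
  # shifting values and the null together preserves p
  set.seed(23)
  v <- rnorm(8, 95, 4)
  p_ref <- one_sample_t_norm100(v)$p_value
  p_shift <- one_sample_t_norm100(v + 13, mu0 = 113)$p_value
  expect_equal(p_ref, p_shift, tolerance = 1e-12)
  # degenerate zero-variance sample away from the null is flagged
  d <- one_sample_t_norm100(c(90, 90, 90))
  expect_true(d$degenerate); expect_equal(d$p_value, 0)
})

test_that("two-sample t matches an independently coded formula", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(24)
  for (rep in 1:25) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    r <- two_sample_t(a, b)
    ref <- textbook_two_sample_t(a, b)
    expect_equal(r$statistic, ref$t, tolerance = 1e-12)
    expect_equal(r$p_value, ref$p, tolerance = 1e-12)
  }
  # welch and rank options run and agree with stats::
  a <- rnorm(10); b <- rnorm(12, 1)
  expect_equal(two_sample_t(a, b, "welch")$p_value,
               t.test(a, b)$p.value, tolerance = 1e-12)
  expect_equal(two_sample_t(a, b, "mann-whitney")$p_value,
               suppressWarnings(wilcox.test(a, b)$p.value),
               tolerance = 1e-12)
})

test_that("variance F-test is symmetric and detects unequal spread", {
  x <- c(1, 2, 3, 4, 5)
  r <- variance_f_test(x, x)
  expect_equal(r$F, 1); expect_equal(r$p_value, 1)
  set.seed(25)
  a <- rnorm(20, sd = 1); b <- rnorm(25, sd = 2)
  expect_equal(variance_f_test(a, b)$p_value,
               variance_f_test(b, a)$p_value, tolerance = 1e-12)
  # agrees with var.test up to the larger/smaller orientation
  expect_equal(variance_f_test(a, b)$p_value,
               stats::var.test(a, b)$p.value, tolerance = 1e-12)
  expect_gte(variance_f_test(a, b)$F, 1)
  # power at SD ratio 3, n = 30
  rej <- vapply(1:60, function(sd) {
    set.seed(3000 + sd)
    variance_f_test(rnorm(30), rnorm(30, sd = 3))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
  expect_error(variance_f_test(c(1, 1), c(2, 2)), "zero variance")
})
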