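test_that("behavior summaries honour their definitions and windows", {
  session <- 1800
  ev <- data.frame(time_s = c(30, 400, 1550, 1600, 1700),
                   behavior = c("bite", "chase", "strike", "strike", "freeze"))
  s <- summarize_behavior(ev, session)
  expect_equal(s$latency_first_bite_s, 30)
  expect_false(s$latency_censored)
  expect_equal(s$aggressive_freq_last5, 2)  # only events after 1500 s
  expect_equal(s$submissive_freq_last5, 1)

  early <- data.frame(time_s = c(100, 200), behavior = c("bite", "chase"))
  s2 <- summarize_behavior(early, session)
  expect_equal(s2$aggressive_freq_last5, 0)

  none <- data.frame(time_s = numeric(0), behavior = character(0))
  s3 <- summarize_behavior(none, session)
  expect_equal(s3$latency_first_bite_s, session)
  expect_true(s3$latency_censored)
})

test_that("pooled t matches the hand formula and the null identity", {
  same <- c(1, 2, 3, 4)
  r <- two_sample_t(same, same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # x = {1,2,3}, y = {4,5,6}: both variances 1, pooled sd 1,
  # t = (2 - 5) / sqrt(2/3) = -3.674235, df = 4
  r2 <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$df, 4)
  expect_equal(r2$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_error(two_sample_t(c(1, 1), c(2, 2)), "zero pooled variance")
})

test_that("pooled-t p-values are uniform under the null", {
  ps <- withr::with_seed(4, vapply(1:500, function(i)
    two_sample_t(stats::rnorm(10), stats::rnorm(10))$p, numeric(1)))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Cohen's d matches hand values and labels magnitudes", {
  # pooled SD exactly 1 by construction (each group sd = 1)
  h <- 1 / sqrt(2)
  x <- c(1 - h, 1 + h); y <- c(-h, h)
  r <- cohens_d(x, y)
  expect_equal(r$d, 1)
  expect_equal(r$d_type, "d_s")
  expect_equal(r$magnitude, "large")
  # x={2,4}, y={1,3}: pooled sd = sqrt(2), d = 1/sqrt(2)
  r2 <- cohens_d(c(2, 4), c(1, 3))
  expect_equal(r2$d, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(r2$magnitude, "medium")
  # identical paired vectors: zero SD of differences is flagged
  r3 <- cohens_d(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(r3$flag, "zero_denominator")
  # paired with keys: alignment by dyad id
  r4 <- cohens_d(c(5, 7, 9), c(1, 2, 3), paired = TRUE,
                 pair_key_x = c("d1", "d2", "d3"),
                 pair_key_y = c("d3", "d1", "d2"))
  expect_equal(r4$d_type, "d_z")
  expect_equal(r4$n, 3)
})

test_that("two-group Welch ANOVA squares the Welch t and degenerate cases behave", {
  withr::with_seed(8, {
    x <- stats::rnorm(12, 0, 1); y <- stats::rnorm(9, 0.8, 2.5)
    w <- welch_anova(c(x, y), rep(c("a", "b"), c(12, 9)))
    tt <- stats::t.test(x, y)  # Welch by default
    expect_equal(w$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  })
  # three identical groups: F = 0, p = 1
  g <- rep(c("a", "b", "c"), each = 4)
  v <- rep(c(1, 2, 3, 4), 3)
  w2 <- welch_anova(v, g)
  expect_equal(w2$statistic, 0, tolerance = 1e-12)
  expect_equal(w2$p, 1, tolerance = 1e-12)
  expect_error(welch_anova(c(1, 1, 2, 3), rep(c("a", "b"), each = 2)),
               "zero-variance")
})

test_that("equal-n equal-variance Welch matches the classical F (two groups)", {
  x <- c(-1.2, -0.3, 0.4, 1.1, 0.2, -0.6)
  # identical spread in both groups: the exact-equality limit where the
  # Welch statistic reduces to the classical one
  v <- c(x, x + 1.4)
  g <- rep(c("a", "b"), each = 6)
  w <- welch_anova(v, g)
  classical <- summary(stats::aov(v ~ g))[[1]]$`F value`[1]
  expect_equal(w$statistic, classical, tolerance = 1e-6)
  expect_equal(w$df[1], 1)
})

test_that("Tukey HSD returns all pairs with adjusted p-values", {
  withr::with_seed(10, {
    v <- c(stats::rnorm(10), stats::rnorm(10, 3), stats::rnorm(10))
    g <- rep(c("a", "b", "c"), each = 10)
    tk <- tukey_hsd(v, g)
    expect_equal(nrow(tk), 3)
    expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
    expect_lt(tk$p_adj[tk$pair == "b-a"], 0.05)
  })
})

test_that("BH adjustment reproduces hand examples and its invariances", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03),
               tolerance = 1e-14)
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5), tolerance = 1e-14)
  withr::with_seed(3, {
    p <- stats::runif(25)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    # step-up monotone: adjusted values ordered like the raw ranks
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    perm <- sample(25)
    expect_equal(bh_adjust(p[perm]), adj[perm])  # order-equivariant
  })
})

test_that("correlation screens omit underpowered pairs and adjust jointly", {
  df <- data.frame(a = c(1, 2, 3, 4, 5), b = c(1.1, 2.2, 2.9, 4.4, 4.8),
                   c = c(5, 1, 4, 2, 3), d = c(1, 2, NA, NA, NA))
  pairs <- data.frame(var1 = c("a", "a", "a"), var2 = c("b", "c", "d"))
  out <- corr_with_bh(df, pairs)
  expect_equal(nrow(out$correlations), 2)
  expect_equal(nrow(out$omitted), 1)
  expect_equal(out$omitted$var2, "d")
  expect_true(all(out$correlations$p_adj >= out$correlations$p))
})
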