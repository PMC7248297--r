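test_that("pooled t reproduces the baseline-age comparison from summaries", {
  res <- two_sample_t(list(n = 27, mean = 23.33, sd = 1.39),
                      list(n = 29, mean = 23.10, sd = 1.37))
  expect_equal(round(res$p, 3), 0.536)
  expect_equal(res$df, 54)
})

test_that("pooled t handles raw data, summaries, and degenerate input alike", {
  res <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$statistic, -sqrt(3 / 2), tolerance = 1e-10)  # -1.2247
  expect_equal(res$df, 4)
  # raw input equals its own summary statistics
  set.seed(71)
  x <- rnorm(14); y <- rnorm(17, 0.5)
  a <- two_sample_t(x, y)
  b <- two_sample_t(list(n = 14, mean = mean(x), sd = sd(x)),
                    list(n = 17, mean = mean(y), sd = sd(y)))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
  # ... and matches the standard pooled t.test
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  idem <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idem$statistic, 0)
  expect_equal(idem$p, 1)
  flat <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(flat$p, 1)
  expect_match(flat$flag, "zero variance")
})

test_that("chi-squared reproduces the baseline gender comparison", {
  res <- chi_square_2x2(rbind(c(13, 14), c(13, 16)))
  expect_equal(round(res$p, 3), 0.803)
  expect_equal(res$df, 1)
  even <- chi_square_2x2(rbind(c(10, 10), c(10, 10)))
  expect_equal(even$statistic, 0)
  expect_equal(even$p, 1)
  # expected-count oracle: all margins 30, expected 15 everywhere
  sk <- chi_square_2x2(rbind(c(20, 10), c(10, 20)))
  expect_equal(sk$statistic, 4 * 25 / 15, tolerance = 1e-10)   # 6.667
  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))), "margin")
})

test_that("paired t reports the mean difference and flags degeneracy", {
  b <- c(10, 11, 12, 13, 14)
  res <- paired_t(b, b + c(0.1, 0.3, 0.2, 0.0, 0.4))
  expect_equal(res$statistic, 2.8284271, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$estimate, 0.2)
  same <- paired_t(b, b)
  expect_equal(same$statistic, 0); expect_equal(same$p, 1)
  expect_equal(same$estimate, 0)
  shift <- paired_t(b, b + 1)
  expect_equal(shift$estimate, 1)
  expect_match(shift$flag, "zero-variance")
})

test_that("BH adjustment follows the step-up definition and its properties", {
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand-computed step-up: p_(i) * m / i with cumulative min from the top
  p <- c(0.003, 0.04, 0.3, 0.7, 0.012)
  expect_equal(bh_fdr(p), c(0.015, 0.0666667, 0.375, 0.7, 0.03),
               tolerance = 1e-6)
  # order-equivariant; and idempotent when the adjustment is saturated
  q <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(bh_fdr(q), q)
  o <- sample(5)
  expect_equal(bh_fdr(p[o]), bh_fdr(p)[o])
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

test_that("mixed ANCOVA matches the least-squares projection oracle", {
  set.seed(81)
  for (rep in 1:3) {
    n <- 16
    wide <- data.frame(subject_id = sprintf("s%02d", 1:n),
                       group = rep(c("control", "training"), each = n / 2),
                       age = rnorm(n, 23, 1.4), gender = rbinom(n, 1, 0.5),
                       education = rnorm(n, 16, 1.2))
    Y <- matrix(rnorm(3 * n), n, 3) +
      outer(as.numeric(wide$group == "training"), c(0, 0.4, 0.8))
    fit <- mixed_anova(make_long(wide, Y), "y")
    orc <- anova_oracle(wide, Y)
    expect_equal(fit$time$statistic, orc$F_time, tolerance = 1e-8)
    expect_equal(fit$interaction$statistic, orc$F_int, tolerance = 1e-8)
    expect_equal(fit$group$statistic, orc$F_group, tolerance = 1e-8)
  }
})

test_that("mixed ANCOVA invariances and degenerate input", {
  set.seed(82)
  n <- 12
  wide <- data.frame(subject_id = sprintf("s%02d", 1:n),
                     group = rep(c("control", "training"), each = n / 2),
                     age = rnorm(n, 23, 1.4), gender = rbinom(n, 1, 0.5),
                     education = rnorm(n, 16, 1.2))
  Y <- matrix(rnorm(3 * n), n, 3)
  f1 <- mixed_anova(make_long(wide, Y), "y")
  # adding a constant to the outcome changes nothing but the intercept
  Y2 <- Y + 100
  f2 <- mixed_anova(make_long(wide, Y2), "y")
  expect_equal(f1$time$statistic, f2$time$statistic, tolerance = 1e-8)
  expect_equal(f1$interaction$statistic, f2$interaction$statistic,
               tolerance = 1e-8)
  # relabeling subjects changes nothing
  wide3 <- wide; wide3$subject_id <- rev(wide$subject_id)
  f3 <- mixed_anova(make_long(wide3, Y), "y")
  expect_equal(f1$interaction$statistic, f3$interaction$statistic,
               tolerance = 1e-8)
  # constant outcome: F = 0, p = 1, flagged
  fc <- mixed_anova(make_long(wide, matrix(5, n, 3)), "y")
  expect_equal(fc$time$statistic, 0); expect_equal(fc$time$p, 1)
  expect_equal(fc$interaction$statistic, 0)
  expect_match(fc$time$flag, "constant")
  # incomplete subjects are named
  long <- make_long(wide, Y)
  expect_error(mixed_anova(long[-1, ], "y"), wide$subject_id[1])
  # gender as a two-level factor is accepted (coded 0/1)
  wide4 <- wide; wide4$gender <- ifelse(wide$gender == 1, "M", "F")
  f4 <- mixed_anova(make_long(wide4, Y), "y")
  expect_equal(f1$interaction$statistic, f4$interaction$statistic,
               tolerance = 1e-8)
})

test_that("interaction test is calibrated under the null and powered under signal", {
  set.seed(83)
  n <- 14
  null_p <- replicate(500, {
    wide <- data.frame(subject_id = sprintf("s%02d", 1:n),
                       group = rep(c("control", "training"), each = n / 2),
                       age = rnorm(n, 23, 1.4), gender = rbinom(n, 1, 0.5),
                       education = rnorm(n, 16, 1.2))
    Y <- matrix(rnorm(3 * n), n, 3)
    mixed_anova(make_long(wide, Y), "y")$interaction$p
  })
  expect_gte(mean(null_p < 0.05), 0.03)
  expect_lte(mean(null_p < 0.05), 0.07)

  pow_p <- replicate(200, {
    m <- 28
    wide <- data.frame(subject_id = sprintf("s%02d", 1:(2 * m)),
                       group = rep(c("control", "training"), each = m),
                       age = rnorm(2 * m, 23, 1.4),
                       gender = rbinom(2 * m, 1, 0.5),
                       education = rnorm(2 * m, 16, 1.2))
    slope <- ifelse(wide$group == "training", 0.45, 0)
    Y <- matrix(rnorm(6 * m, sd = 0.5), 2 * m, 3) + outer(slope, 0:2)
    mixed_anova(make_long(wide, Y), "y")$interaction$p
  })
  expect_gte(mean(pow_p < 0.05), 0.9)
})
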