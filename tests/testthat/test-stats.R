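# Group summaries, location tests, post-hoc families, chi-squared,
# transform decision, effect size and power.

test_that("group summaries use sample sd and CV = sd/mean", {
  s <- group_summary(c(10, 10, 10))
  expect_equal(c(s$mean, s$sd, s$cv), c(10, 0, 0))
  set.seed(1)
  x <- rnorm(50, 20, 4)
  s <- group_summary(x)
  expect_equal(s$mean, mean(x))
  expect_equal(s$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
  expect_equal(s$cv, s$sd / s$mean)
  expect_true(is.na(group_summary(n = 5, mean = 0, sd = 2)$cv))
})

test_that("summary-mode t-tests agree with t.test on raw data", {
  set.seed(2)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1), 10, 2)
    b <- rnorm(sample(5:30, 1), 12, sample(c(2, 5), 1))
    tp <- pooled_t(group_summary(a), group_summary(b))
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(tp$statistic, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(tp$df, unname(ref$parameter))
    expect_equal(tp$p_value, ref$p.value, tolerance = 1e-6)
    tw <- welch_t(group_summary(a), group_summary(b))
    refw <- t.test(a, b)
    expect_equal(tw$statistic, unname(refw$statistic), tolerance = 1e-6)
    expect_equal(tw$df, unname(refw$parameter), tolerance = 1e-6)
    expect_equal(tw$p_value, refw$p.value, tolerance = 1e-6)
  }
})

test_that("t-test degenerate cases follow the zero-variance conventions", {
  a <- group_summary(n = 5, mean = 3, sd = 0)
  expect_equal(pooled_t(a, a)$statistic, 0)
  expect_equal(pooled_t(a, a)$p_value, 1)
  b <- group_summary(n = 5, mean = 4, sd = 0)
  r <- pooled_t(a, b)
  expect_true(is.infinite(r$statistic) && r$degenerate)
  # one zero-sd group under Welch: df tends to n_other - 1
  c2 <- group_summary(n = 21, mean = 4, sd = 2)
  expect_equal(welch_t(a, c2)$df, 20, tolerance = 1e-9)
})

test_that("ANOVA variants match aov/oneway.test and the t-squared identity", {
  set.seed(3)
  g <- list(a = rnorm(15, 10, 2), b = rnorm(25, 11, 4), c = rnorm(20, 13, 3))
  x <- unlist(g); f <- factor(rep(names(g), lengths(g)))
  std <- one_way_anova(g)
  ref <- anova(lm(x ~ f))
  expect_equal(std$statistic, ref$`F value`[1], tolerance = 1e-8)
  expect_equal(std$df, c(2, length(x) - 3))
  expect_equal(std$p_value, ref$`Pr(>F)`[1], tolerance = 1e-8)
  w <- welch_anova(g)
  refw <- oneway.test(x ~ f)
  expect_equal(w$statistic, unname(refw$statistic), tolerance = 1e-8)
  expect_equal(w$df[2], unname(refw$parameter[2]), tolerance = 1e-6)
  expect_equal(w$p_value, refw$p.value, tolerance = 1e-8)
  # identical groups: F = 0, p = 1
  same <- list(a = c(5, 6, 7), b = c(5, 6, 7))
  expect_equal(one_way_anova(same)$statistic, 0)
  expect_equal(one_way_anova(same)$p_value, 1)
  # two-group F = t^2, both families, to 6 decimals
  two <- g[1:2]
  expect_equal(one_way_anova(two)$statistic,
               pooled_t(group_summary(two$a), group_summary(two$b))$statistic^2,
               tolerance = 1e-6)
  expect_equal(welch_anova(two)$statistic,
               welch_t(group_summary(two$a), group_summary(two$b))$statistic^2,
               tolerance = 1e-6)
})

test_that("Welch ANOVA accepts published summaries and lands near printed F", {
  # three-group comparison with strongly reduced mutant mean; from rounded
  # summaries the statistic reproduces only approximately (order 10^2, df2
  # near 70), which is the expected granularity of published tables
  g <- list(WT = group_summary(n = 32, mean = 54, sd = 0.24 * 54),
            HET = group_summary(n = 62, mean = 50.1, sd = 0.22 * 50.1),
            MUT = group_summary(n = 36, mean = 26.3, sd = 0.21 * 26.3))
  w <- welch_anova(g)
  expect_equal(w$df[1], 2)
  expect_gt(w$statistic, 100); expect_lt(w$statistic, 170)
  expect_gt(w$df[2], 60); expect_lt(w$df[2], 80)
  expect_lt(w$p_value, 1e-3)
})

test_that("Levene's test matches car::leveneTest with mean centering", {
  skip_if_not_installed("car")
  set.seed(4)
  x <- c(rnorm(30, 0, 1), rnorm(30, 0, 3))
  f <- rep(c("a", "b"), each = 30)
  mine <- levene(x, f, center = "mean")
  ref <- car::leveneTest(x, factor(f), center = mean)
  expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-8)
  expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-8)
  med <- levene(x, f, center = "median")
  refm <- car::leveneTest(x, factor(f), center = median)
  expect_equal(med$statistic, refm$`F value`[1], tolerance = 1e-8)
  # all-constant input: W = 0 convention
  expect_equal(levene(rep(5, 10), rep(c("a", "b"), 5))$statistic, 0)
})

test_that("Levene detects a 10:1 variance ratio and stays calibrated under the null", {
  set.seed(5)
  rej <- mean(replicate(200, {
    x <- c(rnorm(50, 0, sqrt(10)), rnorm(50, 0, 1))
    levene(x, rep(c("a", "b"), each = 50))$p_value < 0.05
  }))
  expect_gt(rej, 0.9)
  null_rej <- mean(replicate(400, {
    x <- rnorm(60)
    levene(x, rep(c("a", "b", "c"), each = 20))$p_value < 0.05
  }))
  expect_lt(abs(null_rej - 0.05), 0.04)
})

test_that("Tukey HSD matches stats::TukeyHSD and the tabulated q quantile", {
  # published critical value q(0.95; k = 3, df = 10) = 3.88
  expect_equal(qtukey(0.95, 3, 10), 3.88, tolerance = 0.005)
  set.seed(6)
  g <- list(a = rnorm(12, 10, 2), b = rnorm(12, 12, 2), c = rnorm(12, 15, 2))
  x <- unlist(g); f <- factor(rep(names(g), each = 12))
  mine <- tukey_hsd(g)
  ref <- TukeyHSD(aov(x ~ f))$f
  for (r in seq_len(nrow(mine))) {
    pair <- paste(mine$group2[r], mine$group1[r], sep = "-")
    expect_equal(mine$p_value[r], ref[pair, "p adj"], tolerance = 1e-6)
    expect_equal(-mine$diff[r], ref[pair, "diff"], tolerance = 1e-8)
  }
})

test_that("Games-Howell approaches Tukey under equal variances and equal n", {
  set.seed(7)
  # limit case: equal n and exactly equal sample variances, so the two
  # procedures differ only in their df (per-pair 2n-2 vs pooled 3n-3)
  n <- 60
  mk <- function(mu) mu + 2.5 * as.numeric(scale(rnorm(n)))
  g <- list(a = mk(10), b = mk(10.8), c = mk(12))
  th <- tukey_hsd(g); gh <- games_howell(g)
  for (r in seq_len(nrow(th)))
    expect_lt(abs(gh$p_value[r] - th$p_value[r]),
              0.1 * max(th$p_value[r], 0.05))
  # per-pair Welch df never exceeds the pooled df
  expect_true(all(gh$df <= sum(lengths(g)) - 3 + 1e-9))
})

test_that("chi-squared reproduces the Pearson hand computation and Yates shrinks it", {
  expect_equal(chi_square(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_equal(chi_square(matrix(c(10, 10, 10, 10), 2))$p_value, 1)
  tab <- matrix(c(20, 5, 5, 20), 2)
  un <- chi_square(tab, correct = FALSE)
  # hand computation: all expected counts 12.5, X2 = 4 * 7.5^2 / 12.5 = 18
  expect_equal(un$statistic, 18)
  expect_equal(un$df, 1)
  yates <- chi_square(tab, correct = TRUE)
  expect_lt(yates$statistic, un$statistic)
  # r x c table: df = (r-1)(c-1), no correction applied
  t3 <- matrix(c(30, 10, 5, 10, 30, 5, 5, 5, 30), 3)
  expect_equal(chi_square(t3)$df, 4)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2)), "marginal")
  expect_error(chi_square(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("sqrt transform fires on skewed data, not on normal or negative data", {
  set.seed(8)
  n_transformed <- sum(replicate(40, {
    sqrt_transform_if_needed(rnorm(100, 50, 5))$transformed
  }))
  expect_lte(n_transformed, 4)  # calibration: ~alpha of normal samples
  skewed <- rnorm(100)^2
  expect_true(sqrt_transform_if_needed(skewed)$transformed)
  with_neg <- c(skewed[-1], -1)
  expect_warning(res <- sqrt_transform_if_needed(with_neg), "negative")
  expect_false(res$transformed)
})

test_that("Cohen's d follows the pooled-sd formula and its scale property", {
  a <- group_summary(n = 16, mean = 29, sd = 9.86)
  b <- group_summary(n = 16, mean = 37.2, sd = 9.672)
  expect_equal(cohen_d(a, b), 0.84, tolerance = 0.005)
  expect_equal(cohen_d(a, a), 0)
  a2 <- group_summary(n = 16, mean = 29, sd = 2 * 9.86)
  b2 <- group_summary(n = 16, mean = 37.2, sd = 2 * 9.672)
  expect_equal(cohen_d(a2, b2), cohen_d(a, b) / 2)
  expect_error(cohen_d(group_summary(n = 4, mean = 1, sd = 0),
                       group_summary(n = 4, mean = 1, sd = 0)), "undefined")
})

test_that("noncentral-t power matches a Monte-Carlo rejection-rate estimate", {
  expect_equal(power_two_sample_t(0, 10), 0.05, tolerance = 1e-9)
  set.seed(9)
  nmc <- 40000
  for (case in list(c(0.5, 20), c(0.84, 16), c(1.2, 8))) {
    d <- case[1]; n <- case[2]
    # vectorised simulation oracle: pooled t on nmc paired samples
    a <- matrix(rnorm(n * nmc), n); b <- matrix(rnorm(n * nmc, d), n)
    va <- apply(a, 2, var); vb <- apply(b, 2, var)
    tstat <- (colMeans(b) - colMeans(a)) /
      sqrt((va + vb) / 2 * (2 / n))
    rej <- mean(abs(tstat) > qt(0.975, 2 * n - 2))
    expect_lt(abs(power_two_sample_t(d, n) - rej),
              3 * sqrt(0.25 / nmc) + 0.005)
  }
})

test_that("power is monotone and the sample-size search is exactly minimal", {
  d <- 0.84
  p1 <- vapply(2:40, function(n) power_two_sample_t(d, n), 0)
  expect_true(all(diff(p1) > 0))
  p2 <- vapply(seq(0.1, 2, by = 0.1),
               function(dd) power_two_sample_t(dd, 16), 0)
  expect_true(all(diff(p2) > 0))
  for (target in c(0.5, 0.8, 0.9, 0.95)) {
    n <- required_n_two_sample_t(d, target)
    expect_gte(power_two_sample_t(d, n), target)
    expect_lt(power_two_sample_t(d, n - 1), target)
  }
  # 1/d^2 scaling: doubling d roughly quarters the required n
  n1 <- required_n_two_sample_t(0.4, 0.9)
  n2 <- required_n_two_sample_t(0.8, 0.9)
  expect_lt(abs(n2 - n1 / 4) / (n1 / 4), 0.25)
  expect_error(required_n_two_sample_t(0, 0.9), "positive")
})
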