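test_that("summary tables report mean, SEM and range exactly", {
  s <- summarize_values(c(1, 2, 3), "demo", "um")
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3))
  expect_equal(c(s$min, s$max), c(1, 3))
  expect_equal(summarize_values(rep(4.2, 10))$sem, 0)
  expect_error(summarize_values(1), "SEM")

  set.seed(71)
  x <- rlnorm(50)
  s2 <- summarize_values(x)
  expect_true(s2$min <= s2$mean && s2$mean <= s2$max)
})

test_that("frequency curves are conservative and bin as specified", {
  fc <- frequency_curve(c(0.05, 0.05, 0.15), start = 0, bin_width = 0.1,
                        n_bins = 2)
  expect_equal(fc$freq, c(2 / 3, 1 / 3))
  expect_equal(sum(fc$freq), 1)

  one <- frequency_curve(rep(0.25, 7), start = 0, bin_width = 0.1,
                         n_bins = 5)
  expect_equal(sum(one$freq == 1), 1)

  # overflow folds into the last bin with a warning, conserving mass
  expect_warning(
    ov <- frequency_curve(c(0.05, 0.95), start = 0, bin_width = 0.1,
                          n_bins = 3),
    "beyond the last bin")
  expect_equal(sum(ov$freq), 1)
  expect_equal(attr(ov, "n_overflow"), 1L)
  expect_error(frequency_curve(numeric(0), 0, 0.1, 3), "empty")
  expect_error(frequency_curve(c(-1, 1), 0, 0.1, 11), "below")

  # a uniform sample fills many bins nearly evenly
  set.seed(72)
  u <- runif(5000)
  fu <- frequency_curve(u, 0, 0.1, 10)
  chi <- chisq.test(fu$count, p = rep(0.1, 10))
  expect_gt(chi$p.value, 1e-4)

  # reporting specs for the three variable families
  expect_equal(histogram_spec("length")$bin_width, 0.08)
  expect_equal(histogram_spec("area")$n_bins, 9)
  expect_equal(histogram_spec("volume")$bin_width, 0.03)
})

test_that("spearman_rho equals the rank-formula oracle and handles ties as midranks", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)

  set.seed(73)
  for (i in 1:25) {
    x <- sample(1000, 30)            # distinct -> tie-free
    y <- sample(1000, 30)
    expect_equal(spearman_rho(x, y), oracle_spearman_noties(x, y),
                 tolerance = 1e-12)
    expect_equal(spearman_rho(x, y), spearman_rho(y, x))
  }
  # with ties: agree with the midrank definition used by stats::cor
  for (i in 1:10) {
    x <- sample(5, 40, replace = TRUE)
    y <- x + sample(3, 40, replace = TRUE)
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rho(1:3, 1:4), "length")
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "constant")
})

test_that("group comparisons pick the right test and calibrate against permutation", {
  set.seed(74)
  a <- rnorm(15); b <- a   # identical groups (all ties -> approximate p)
  same <- suppressWarnings(compare_groups(a, b))
  expect_equal(same$test, "mann_whitney")
  expect_gt(same$p_value, 0.9)
  expect_equal(same$statistic, 15 * 15 / 2)  # U at its null centre

  sep <- compare_groups(rnorm(50), rnorm(50, 5))
  expect_lt(sep$p_value, 0.001)

  # small-n p-value against a full permutation oracle of the rank-sum
  x <- c(1.2, 3.1, 2.2, 5.0); y <- c(2.9, 4.4, 6.1, 7.2)
  got <- compare_groups(x, y)$p_value
  pooled <- c(x, y); n <- length(x)
  combs <- combn(8, n)
  r_obs <- sum(rank(pooled)[1:n])
  r_all <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]))
  p_perm <- mean(abs(r_all - n * 9 / 2) >= abs(r_obs - n * 9 / 2))
  expect_equal(got, p_perm, tolerance = 1e-12)

  # three equal-mean groups: F fluctuates around 1 under the null
  f <- replicate(200, {
    g <- replicate(3, rnorm(20), simplify = FALSE)
    compare_groups(g)$statistic
  })
  expect_equal(mean(f), 1, tolerance = 0.25)
  expect_equal(compare_groups(rnorm(10), rnorm(10), rnorm(10))$test,
               "anova_oneway")
  expect_error(compare_groups(rnorm(5)), "at least 2 groups")
  expect_error(compare_groups(rnorm(5), 1), "at least 2 observations")
})
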