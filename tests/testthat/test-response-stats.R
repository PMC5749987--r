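test_that("antisymmetric differences give Z = 0 and p = 1", {
  w <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3))
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
  expect_equal(w$effect_size, 0)
})

test_that("all-positive differences at n = 8 match the exact distribution", {
  w <- wilcoxon_signed_rank(c(0.8, 1.1, 2.4, 3.7, 4.1, 5.6, 6.2, 7.9))
  expect_true(w$exact)
  expect_equal(w$p_value, 2 / 2^8)
  expect_equal(w$p_value, signflip_p(c(0.8, 1.1, 2.4, 3.7, 4.1, 5.6, 6.2,
                                       7.9)))
})

test_that("reported p equals sign-flip enumeration for small untied samples", {
  # for n <= 15 without ties the implementation reports the exact
  # signed-rank p, which must coincide with brute-force enumeration
  # (the normal approximation is deliberately not bounded here: the
  # discrete distribution has point masses ~0.03 at n = 6, so no
  # continuous approximation tracks it tightly)
  set.seed(5)
  checked <- 0
  for (i in 1:40) {
    n <- sample(6:12, 1)
    d <- round(rnorm(n, mean = runif(1, -1, 1)), 3)
    d <- d[d != 0]
    if (length(d) < 6 || any(duplicated(abs(d)))) next
    w <- wilcoxon_signed_rank(d)
    expect_true(w$exact)
    expect_equal(w$p_value, signflip_p(d), tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gt(checked, 10)
})

test_that("zero differences are dropped and the degenerate case flagged", {
  w <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3, 4, -1, 0.5))
  expect_equal(w$n_pairs, 6)
  all0 <- wilcoxon_signed_rank(rep(0, 10))
  expect_true(all0$degenerate)
  expect_equal(all0$p_value, 1)
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 0)), "at least 5")
})

test_that("paired t matches hand-computed arithmetic and reported d", {
  t5 <- paired_t(c(1, 2, 3, 4, 5))
  expect_equal(t5$statistic, 3 / (sd(1:5) / sqrt(5)))
  expect_equal(t5$statistic, 4.2426, tolerance = 1e-4)
  expect_equal(t5$df, 4)
  # all-zero differences
  t0 <- paired_t(rep(0, 6))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_equal(t0$effect_size, 0)
  # printed night-time comparison: t = 1.092 with 31 pairs gives d = 0.20
  expect_equal(round(cohens_d(1.092, 31), 2), 0.20)
  # zero-variance nonzero-mean differences flag an infinite t
  ti <- paired_t(rep(2, 6))
  expect_true(is.infinite(ti$statistic) && ti$degenerate)
})

test_that("effect-size conventions reproduce the printed values", {
  expect_equal(round(effect_size_r(2.29, 31), 2), 0.41)
  expect_equal(round(effect_size_r(2.77, 31), 2), 0.50)
  # printed Z = 2.8 is itself rounded; 2.8/sqrt(32) = 0.495
  expect_lte(abs(effect_size_r(2.8, 16, "r_sqrt_obs") - 0.50), 0.00505)
  expect_equal(effect_size_r(0, 10), 0)
  expect_equal(effect_size_r(0, 10, "r_sqrt_obs"), 0)
})

test_that("the normality gate selects the expected branch", {
  set.seed(7)
  picks <- replicate(200, choose_test(rnorm(30))$test)
  rate <- mean(picks == "paired_t")
  expect_gt(rate, 0.90)   # gate at alpha = 0.05 keeps ~95% of normal samples
  expect_lt(rate, 0.99)
  picks_c <- replicate(200, choose_test(rcauchy(30))$test)
  expect_gt(mean(picks_c == "wilcoxon"), 0.7)
  expect_error(choose_test(rnorm(4)), "at least 5")
  expect_equal(choose_test(rep(1, 10))$test, "wilcoxon")
})

test_that("both tests are invariant to a common additive shift", {
  set.seed(11)
  a <- rnorm(20); b <- rnorm(20)
  w1 <- wilcoxon_signed_rank(a, b)
  w2 <- wilcoxon_signed_rank(a + 5, b + 5)
  expect_equal(w1$statistic, w2$statistic)
  expect_equal(w1$p_value, w2$p_value)
  t1 <- paired_t(a, b)
  t2 <- paired_t(a + 5, b + 5)
  expect_equal(t1$statistic, t2$statistic)
  # t is invariant to positive rescaling
  t3 <- paired_t(3 * a, 3 * b)
  expect_equal(t1$statistic, t3$statistic)
})

test_that("the 30-s whistle comparison uses the total-observation r", {
  w <- whistles_30s_comparison(before = c(1, 2, 3, 4, 5, 6, 7, 9),
                               after = c(3, 5, 4, 8, 9, 12, 10, 15))
  expect_equal(w$convention, "r_sqrt_obs")
  expect_equal(w$effect_size, abs(w$statistic) / sqrt(2 * w$n_pairs))
  same <- whistles_30s_comparison(1:8, 1:8)
  expect_equal(same$statistic, 0)
  expect_true(same$degenerate)
})

test_that("a simulated post-blast whistle surge is reliably detected", {
  hits <- 0
  for (r in 1:100) {
    pairs <- simulate_whistle_pairs(n_undets = 16, base_mean = 5, surge = 2.5,
                                    seed = 500 + r)
    w <- whistles_30s_comparison(pairs$before, pairs$after)
    hits <- hits + (w$p_value < 0.05 && w$statistic > 0)
  }
  expect_gte(hits / 100, 0.8)
})
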