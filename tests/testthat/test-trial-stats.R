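test_that("geometric mean CI behaves on closed-form cases", {
  z <- geometric_mean_ci(c(10, 10, 10))
  expect_equal(z$gm, 10)
  expect_equal(z$ci_lo, 10)
  expect_equal(z$ci_hi, 10)
  expect_equal(geometric_mean_ci(c(1, 100))$gm, 10)
  expect_error(geometric_mean_ci(c(1, 0, 2)), "positive")
  expect_error(geometric_mean_ci(5), "at least 2")
})

test_that("95% CI coverage of the geometric mean is nominal", {
  set.seed(71)
  gm <- 0.3
  sdlog <- 0.5
  hits <- vapply(seq_len(1000), function(i) {
    x <- rlnorm(52, log(gm), sdlog)
    ci <- geometric_mean_ci(x)
    ci$ci_lo <= gm && gm <= ci$ci_hi
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.95), 0.02)
})

test_that("relative bioavailability equals the ratio identity on paired data", {
  expect_equal(relative_bioavailability(c(1, 2, 3), c(1, 2, 3))$summary$gm, 1)
  ref <- c(0.2, 0.3, 0.25, 0.31)
  got <- relative_bioavailability(1.76 * ref, ref)
  expect_equal(got$summary$gm, 1.76, tolerance = 1e-12)
  # GM of individual ratios == ratio of GMs for complete pairs
  set.seed(5)
  a <- rlnorm(52, log(0.4), 0.5)
  b <- rlnorm(52, log(0.25), 0.5)
  rb <- relative_bioavailability(a, b)
  expect_equal(rb$summary$gm, rb$gm_ratio_of_gms, tolerance = 1e-12)
  expect_error(relative_bioavailability(1:3, 1:4), "equal length")
  expect_error(relative_bioavailability(c(1, -1), c(1, 1)), "positive")
})

test_that("paired log-scale test handles nulls, caps, and type-I error", {
  x <- rep(c(0.2, 0.3, 0.4), length.out = 10)
  same <- paired_test_bonferroni(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_raw, 1)
  # Bonferroni multiplies and caps at 1, never lowers
  set.seed(8)
  a <- rlnorm(10, 0, 0.3)
  b <- rlnorm(10, 0, 0.3)
  raw <- paired_test_bonferroni(a, b, k = 1)
  adj <- paired_test_bonferroni(a, b, k = 4)
  expect_gte(adj$p_adj, raw$p_raw)
  expect_lte(adj$p_adj, 1)
  expect_equal(min(1, 4 * raw$p_raw), adj$p_adj)
  # type-I error at alpha 0.05 over 2000 null replicates of n = 52 pairs
  set.seed(99)
  sdlog <- 0.223
  rej <- vapply(seq_len(2000), function(i) {
    d <- rnorm(52, 0, sdlog) # log-ratio differences under GM ratio 1
    t <- sqrt(52) * mean(d) / sd(d)
    2 * pt(-abs(t), df = 51) < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("paired sample size reproduces the convention arithmetic", {
  expect_equal(sample_size_paired_log(0.223, 1.3, 0.8, 0.05, log_base = 10,
                                      method = "normal"), 31L)
  expect_equal(sample_size_paired_log(0, 1.3), 2L)
  expect_error(sample_size_paired_log(0.223, 1.0), "exceed 1")
  # monotone: n non-decreasing in sd, non-increasing in detect ratio
  sds <- seq(0.1, 0.5, by = 0.05)
  ns <- vapply(sds, sample_size_paired_log, integer(1), detect_ratio = 1.3)
  expect_true(all(diff(ns) >= 0))
  ratios <- seq(1.1, 2, by = 0.1)
  nr <- vapply(ratios, function(r) sample_size_paired_log(0.3, r), integer(1))
  expect_true(all(diff(nr) <= 0))
})

test_that("the convention sweep brackets the printed recruitment arithmetic", {
  sweep <- sample_size_conventions()
  expect_equal(nrow(sweep), 8)
  # the stated inputs under-determine n; the standard conventions span a
  # bracket that contains 44 (base-10 logs with a Bonferroni-4 alpha land
  # nearest), and inflating 44 by 20% dropout gives the recruited 52
  expect_true(min(sweep$n) <= 44 && 44 <= max(sweep$n))
  b10 <- sweep[sweep$log_base == 10 & sweep$n_comparisons == 4, ]
  expect_true(all(abs(b10$n - 44) <= 2))
  expect_equal(inflate_for_dropout(44, 0.20), 52L)
  expect_equal(inflate_for_dropout(10, 0.20), 12L)
  expect_error(inflate_for_dropout(10, 1.0), "\\[0, 1\\)")
})

test_that("groupwise ANOVA with Bonferroni pairwise comparisons", {
  g <- rep(c("a", "b", "c"), each = 4)
  same <- groupwise_anova_bonferroni(rep(c(1, 2, 3, 4), 3), g)
  expect_lt(same$f, 1e-20)
  expect_true(all(same$pairwise$p_adj == 1))
  set.seed(2)
  sep <- groupwise_anova_bonferroni(c(rnorm(3, 0, 0.1), rnorm(3, 10, 0.1)),
                                    rep(c("lo", "hi"), each = 3))
  expect_lt(sep$pairwise$p_adj, 0.001)
  expect_error(groupwise_anova_bonferroni(1:3, rep("only", 3)), "2 groups")
  expect_error(groupwise_anova_bonferroni(1:3, c("a", "a", "b")), "n >= 2")
})
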