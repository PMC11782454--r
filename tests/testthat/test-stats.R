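test_that("exact rank-sum p-values equal complete enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)

  set.seed(2)
  for (m in 1:5) {
    for (n in 1:(10 - m)) {
      x <- sample(100, m); y <- setdiff(sample(100, m + n), x)[seq_len(n)]
      expect_equal(wilcoxon_rank_sum(x, y), enumerate_ranksum_p(x, y),
                   tolerance = 1e-12, info = sprintf("m=%d n=%d", m, n))
    }
  }
})

test_that("rank-sum normal approximation tracks the exact branch", {
  set.seed(13)
  x <- rnorm(10); y <- rnorm(10, 0.5)
  p_exact <- wilcoxon_rank_sum(x, y, exact_max_n = 20)
  p_norm <- wilcoxon_rank_sum(x, y, exact_max_n = 0)
  expect_lt(abs(p_exact - p_norm), 0.02)

  # identical multisets give p ~ 1 and agree with the reference test with ties
  z <- rep(c(1, 2, 3), 10)
  expect_gt(wilcoxon_rank_sum(z, z), 0.9)
  suppressWarnings(ref <- stats::wilcox.test(c(z, 9), z)$p.value)
  expect_equal(wilcoxon_rank_sum(c(z, 9), z), ref, tolerance = 1e-9)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(31)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, NaN)), "finite")
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  p <- runif(20)
  expect_true(all(bh_adjust(p) <= 1))
  expect_true(all(diff(bh_adjust(p)[order(p)]) >= 0))  # monotone in order stats
})

test_that("control-based gene tests flag shifted targets and stay calibrated", {
  set.seed(17)
  ctrl <- rnorm(50, 0, 0.2)
  gf <- data.frame(
    guide_id = sprintf("g%02d", 1:60),
    target_id = c(rep("hit", 5), rep("null", 5), rep("ctrl", 50)),
    fitness = c(rnorm(5, -3, 0.2), sample(ctrl, 5), ctrl))
  res <- condition_gene_test(gf)
  expect_lt(res$p[res$target_id == "hit"], 0.01)
  expect_gt(res$p[res$target_id == "null"], 0.05)

  # a target equal to the control median is not significant
  gf2 <- data.frame(guide_id = c("a", "b", "c", sprintf("c%02d", 1:20)),
                    target_id = c(rep("t", 3), rep("ctrl", 20)),
                    fitness = c(rep(median(ctrl[1:20]), 3), ctrl[1:20]))
  expect_gt(condition_gene_test(gf2)$p, 0.5)
  expect_error(condition_gene_test(gf2[1:3, ]), "control")
})

test_that("null p-values from the rank-sum test are uniform", {
  set.seed(29)
  p <- replicate(500, wilcoxon_rank_sum(rnorm(5), rnorm(50)))
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
  expect_lt(mean(p < 0.05), 0.08)
})

test_that("between-condition tests detect separation and respect the null", {
  a <- data.frame(target_id = "t", fitness = c(-2.4, -2.5, -2.6, -2.5, -2.4))
  b <- data.frame(target_id = "t", fitness = c(2.5, 2.6, 2.4, 2.6, 2.5))
  res <- between_condition_test(a, b)
  expect_equal(res$p, 2 / choose(10, 5), tolerance = 1e-12)

  same <- data.frame(target_id = "t", fitness = rep(c(0.3, -0.1, 0.2), 4))
  expect_gt(between_condition_test(same, same)$p, 0.9)
})

test_that("a pure-null screen keeps the BH discovery fraction at bay", {
  set.seed(41)
  n_targets <- 2000
  fa <- data.frame(target_id = rep(sprintf("t%04d", 1:n_targets), each = 5),
                   fitness = rnorm(5 * n_targets, 0, 0.3))
  fb <- data.frame(target_id = fa$target_id,
                   fitness = rnorm(5 * n_targets, 0, 0.3))
  res <- between_condition_test(fa, fb)
  expect_lte(mean(res$p_adj < 0.05), 0.05)
})

test_that("impact scores reproduce the published worked examples", {
  expect_equal(round(impact_score(-3.20, 1.95), 2), 3.64)   # psbJ
  expect_equal(round(impact_score(0.64, -4.54), 2), -3.66)  # pmgA
  expect_equal(impact_score(1.7, 1.7), 0)
  # antisymmetry
  set.seed(6)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(impact_score(x, y), -impact_score(y, x))
})

test_that("combined scores multiply impact by evidence", {
  expect_equal(combined_score(3.2, 1.0), 0)
  expect_equal(combined_score(2, 0.01), 4)
  expect_equal(combined_score(-3, 0.001), -9)
  expect_error(combined_score(1, 0), "cap")
  expect_error(combined_score(1, 1.2), "<= 1")
})

test_that("hit classes use strict unit thresholds", {
  expect_equal(classify_hits(c(-1.5, -1, 0, 1, 1.0001)),
               c("depleted", "neutral", "neutral", "neutral", "enriched"))
  expect_error(classify_hits(NA_real_), "finite")
})
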