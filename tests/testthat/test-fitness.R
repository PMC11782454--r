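test_that("median-of-ratios size factors match hand computation", {
  m <- cbind(s1 = c(2, 3, 5), s2 = c(4, 6, 10))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  ident <- cbind(a = c(5, 7, 9), b = c(5, 7, 9), c = c(5, 7, 9))
  expect_equal(unname(size_factors(ident)), c(1, 1, 1))

  # scale equivariance: multiplying one sample by c scales its factor by c
  # relative to the others (factors are defined up to a common constant)
  f0 <- size_factors(m)
  m2 <- m; m2[, 2] <- m2[, 2] * 3
  f2 <- size_factors(m2)
  expect_equal((f2[2] / f2[1]) / (f0[2] / f0[1]), 3, tolerance = 1e-12,
               ignore_attr = TRUE)

  # columns that are scalar multiples reproduce the scalars up to a constant
  base <- c(10, 20, 40, 80)
  m3 <- cbind(base, 2 * base, 5 * base)
  f3 <- unname(size_factors(m3))
  expect_equal(f3 / f3[1], c(1, 2, 5), tolerance = 1e-12)

  allzero <- cbind(c(0, 5), c(3, 0))
  expect_error(size_factors(allzero), "pseudocount")
})

test_that("size factors agree with the reference count-normalization oracle", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  m <- matrix(rnbinom(600, mu = 80, size = 5) + 1L, nrow = 100)
  colnames(m) <- paste0("s", 1:6)
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("log2 fold-change profiles are computed per replicate vs generation 0", {
  fx <- tiny_screen_fixture()
  sf <- stats::setNames(rep(1, 4), fx$sheet$sample)
  prof <- log2fc_profiles(fx$counts, sf, fx$sheet, pseudocount = 0)
  g1 <- prof[prof$guide_id == "g1_1", ]
  expect_equal(g1$log2fc[order(g1$generation)], c(0, -4, -8, -10))
  ctrl <- prof[prof$guide_id == "ctrl_1", ]
  expect_equal(ctrl$log2fc, rep(0, 4))

  # pseudocount: count 0 at t, 100 at t0 -> log2(0.5 / 100.5)
  m <- rbind(gz = c(100L, 0L), ref = c(50L, 50L))
  colnames(m) <- c("A_r1_g0", "A_r1_g4")
  sheet <- data.frame(sample = colnames(m), condition = "A", replicate = 1,
                      generation = c(0, 4))
  p <- log2fc_profiles(m, c(A_r1_g0 = 1, A_r1_g4 = 1), sheet, 0.5)
  expect_equal(p$log2fc[p$guide_id == "gz" & p$generation == 4],
               log2(0.5 / 100.5), tolerance = 1e-12)

  bad_sheet <- sheet; bad_sheet$generation <- c(4, 8)
  expect_error(log2fc_profiles(m, c(1, 1), bad_sheet), "generation-0")
})

test_that("AUC fitness integrates the trapezoid and normalizes by final
           generation", {
  expect_equal(auc_fitness(c(0, 4, 8, 10), c(0, -2, -4, -5), FALSE), -25)
  expect_equal(auc_fitness(c(0, 4, 8, 10), c(0, -2, -4, -5)), -2.5)
  expect_equal(auc_fitness(c(0, 4, 8, 10), rep(0, 4)), 0)
  for (c0 in c(-1.5, 0.7, 3)) {
    expect_equal(auc_fitness(c(0, 4, 8, 10), c(0, c0, c0, c0)), 0.8 * c0)
  }
  expect_error(auc_fitness(0, 0), "at least 2")
  expect_error(auc_fitness(c(4, 8), c(1, 2)), "generation 0")
})

test_that("AUC fitness agrees with a reference trapezoid and is linear", {
  skip_if_not_installed("pracma")
  set.seed(8)
  for (i in 1:10) {
    g <- c(0, sort(runif(4, 1, 12)))
    y <- c(0, rnorm(4))
    expect_equal(auc_fitness(g, y, normalize = FALSE), pracma::trapz(g, y),
                 tolerance = 1e-12)
  }
  g <- c(0, 4, 8, 10)
  y1 <- c(0, rnorm(3)); y2 <- c(0, rnorm(3))
  a <- 2.5; b <- -1.25
  expect_equal(auc_fitness(g, a * y1 + b * y2),
               a * auc_fitness(g, y1) + b * auc_fitness(g, y2),
               tolerance = 1e-12)
})

test_that("guide weights follow clamped mean correlation times efficiency", {
  same <- rbind(c(-1, -2, -3), c(-1, -2, -3), c(-1, -2, -3))
  expect_equal(guide_weights(same), rep(1 / 3, 3))

  mixed <- rbind(c(-1, -2, -3), c(-1, -2, -3), c(1, 2, 3))
  expect_equal(guide_weights(mixed), c(0.5, 0.5, 0))

  expect_equal(guide_weights(c(1, 2, 3)), 1)           # single guide

  # all mutually anti-correlated -> uniform fallback
  anti <- rbind(c(1, -1, 1), c(-1, 1, -1))
  expect_equal(guide_weights(anti), c(0.5, 0.5))

  # efficiency prior scales the weights
  w <- guide_weights(same, efficiency = c(1, 1, 0.5))
  expect_equal(w, c(0.4, 0.4, 0.2))
  expect_equal(sum(w), 1)
})

test_that("gene fitness is the weighted mean with a percentile bootstrap CI", {
  r <- gene_fitness(c(2, 2, 2), c(0.2, 0.5, 0.3))
  expect_equal(r$fitness, 2)
  expect_equal(c(r$ci_lo, r$ci_hi), c(2, 2))

  expect_equal(gene_fitness(c(1, 3), c(0.75, 0.25))$fitness, 1.5)

  r2 <- gene_fitness(c(0, 0, 0, 4), bootstrap_reps = 1000, seed = 1)
  expect_equal(r2$fitness, 1.0)
  expect_lte(r2$ci_lo, 1.0)
  expect_gte(r2$ci_hi, 1.0)
  expect_equal(sum(r2$weights), 1)

  # uniform weights equal the arithmetic mean
  set.seed(4)
  f <- rnorm(7)
  expect_equal(gene_fitness(f, bootstrap_reps = 10)$fitness, mean(f))

  s <- gene_fitness(5, bootstrap_reps = 10)
  expect_equal(c(s$fitness, s$ci_lo, s$ci_hi), c(5, 5, 5))
  expect_error(gene_fitness(numeric(0)), "empty")
})

test_that("replicate-mean AUC equals the mean of per-replicate AUCs", {
  fx <- tiny_screen_fixture()
  sheet2 <- rbind(fx$sheet,
                  within(fx$sheet, {replicate <- 2
                                    sample <- sub("rep1", "rep2", sample)}))
  counts2 <- cbind(fx$counts, fx$counts %/% 2L + 1L)
  colnames(counts2) <- sheet2$sample
  sf <- stats::setNames(rep(1, 8), sheet2$sample)
  prof <- log2fc_profiles(counts2, sf, sheet2, pseudocount = 0.5)
  mean_scores <- guide_fitness_scores(prof)
  rep_scores <- guide_fitness_scores(prof, by_replicate = TRUE)
  agg <- stats::aggregate(fitness ~ guide_id + condition, rep_scores, mean)
  mrg <- merge(mean_scores, agg, by = c("guide_id", "condition"))
  expect_equal(mrg$fitness.x, mrg$fitness.y, tolerance = 1e-12)
})
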