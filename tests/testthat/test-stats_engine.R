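cfg_fast <- stats_config(n_permutations = 1000, seed = 42)

test_that("paired permutation t-test behaves at the extremes", {
  x <- rnorm(10)
  r <- perm_ttest_paired(x, x, cfg_fast)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_mc, 1)
  expect_match(r$flag, "zero-variance")

  withr::local_seed(1)
  y <- rnorm(12)
  r2 <- perm_ttest_paired(y + 10 + rnorm(12, sd = 1e-3), y, cfg_fast)
  expect_lte(r2$p_mc, 2 / (cfg_fast$n_permutations + 1))
  expect_equal(r2$df, 11)
  expect_error(perm_ttest_paired(1, 1:2), "equal length")
})

test_that("Monte-Carlo paired-t p matches exact sign-flip enumeration", {
  # brute-force oracle: all 2^5 sign patterns of the differences
  exact_p <- function(d) {
    n <- length(d)
    tstat <- function(v) mean(v) / (sd(v) / sqrt(n))
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    tp <- apply(signs, 1, function(s) tstat(d * s))
    mean(abs(tp) >= abs(tstat(d)) - 1e-12)
  }
  withr::local_seed(2)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5, mean = 0.8)
    p_exact <- exact_p(x - y)
    p_mc <- perm_ttest_paired(x, y, stats_config(n_permutations = 4000,
                                                 seed = i))$p_mc
    expect_lt(abs(p_mc - p_exact), 0.02)
  }
})

test_that("paired-t type-I error sits at the nominal level", {
  withr::local_seed(3)
  rej <- replicate(400, {
    x <- rnorm(12); y <- rnorm(12)
    perm_ttest_paired(x, y, stats_config(n_permutations = 400))$p_mc <= 0.05
  })
  ci <- 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(rej) - 0.05), ci + 0.005)
})

test_that("permutation ANOVA recovers hand-computed F on a balanced toy", {
  # 2x2 design, 2 observations per cell, pure main effect of A:
  #   a1: 1, 3, 2, 4   a2: 5, 7, 6, 8  (B balanced within A)
  y <- c(1, 3, 2, 4, 5, 7, 6, 8)
  fac <- data.frame(A = rep(c("a1", "a2"), each = 4),
                    B = rep(c("b1", "b1", "b2", "b2"), 2))
  res <- perm_anova(y, fac, stats_config(n_permutations = 2000, seed = 1))
  # hand-computed: SS_A = 4*(2.5-4.5)^2 + 4*(6.5-4.5)^2 = 32,
  # within-cell SS = 2 per cell * 4 cells = 8 on df 4 -> MSE = 2
  grand <- mean(y)
  ss_a <- sum(tapply(y, fac$A, length) * (tapply(y, fac$A, mean) - grand)^2)
  expect_equal(ss_a, 32)
  expect_equal(res$A$statistic, 32 / 2)
  expect_equal(res$A$df, c(1, 4))
  expect_equal(res$B$statistic, 2 / 2)    # SS_B = 2
  expect_gt(res$B$p_mc, 0.3)

  # observed F agrees with an independent Type II implementation
  skip_if_not_installed("car")
  fit <- stats::lm(y ~ A * B, data = cbind(fac, y = y),
                   contrasts = list(A = "contr.sum", B = "contr.sum"))
  ca <- car::Anova(fit, type = 2)
  expect_equal(res$A$statistic, ca[["F value"]][1])
  expect_equal(res$B$statistic, ca[["F value"]][2])
  expect_equal(res$`A:B`$statistic, ca[["F value"]][3])
})

test_that("ANOVA Monte-Carlo p matches exact label enumeration", {
  y <- c(1, 3, 2, 4, 5, 7, 6, 8)
  fac <- data.frame(A = rep(c("a1", "a2"), each = 4),
                    B = rep(c("b1", "b1", "b2", "b2"), 2))
  # oracle: enumerate all 70 relabelings of which 4 rows carry a1
  f_of_a <- function(lab) {
    f2 <- fac; f2$A <- lab
    fit_full <- stats::lm(y ~ A * B, data = cbind(f2, y = y))
    red <- stats::lm(y ~ B, data = cbind(f2, y = y))
    add <- stats::lm(y ~ B + A, data = cbind(f2, y = y))
    mse <- sum(residuals(fit_full)^2) / fit_full$df.residual
    (sum(residuals(red)^2) - sum(residuals(add)^2)) / mse
  }
  f_obs <- f_of_a(fac$A)
  combos <- utils::combn(8, 4)
  f_all <- apply(combos, 2, function(idx) {
    lab <- rep("a2", 8); lab[idx] <- "a1"
    f_of_a(lab)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  res <- perm_anova(y, fac, stats_config(n_permutations = 4000, seed = 2))
  expect_lt(abs(res$A$p_mc - p_exact), 0.02)
})

test_that("identical groups give F = 0 and empty cells are fatal", {
  y <- rep(c(1, 2, 3), 4)       # every cell holds (1, 2, 3)
  fac <- data.frame(A = rep(c("a1", "a2"), each = 6),
                    B = rep(rep(c("b1", "b2"), each = 3), 2))
  res <- perm_anova(y, fac, stats_config(n_permutations = 200, seed = 3))
  expect_equal(res$A$statistic, 0, tolerance = 1e-12)
  expect_gt(res$A$p_mc, 0.9)

  bad <- data.frame(A = c("a1", "a1", "a2", "a2"),
                    B = c("b1", "b1", "b1", "b2"))
  expect_error(perm_anova(1:4, bad, cfg_fast), "empty")
})

test_that("ANOVA type-I error is nominal under the null", {
  withr::local_seed(4)
  rej <- replicate(300, {
    y <- rnorm(16)
    fac <- data.frame(A = rep(c("a1", "a2"), 8),
                      B = rep(c("b1", "b2"), each = 8))
    perm_anova(y, fac, stats_config(n_permutations = 200))$A$p_mc <= 0.05
  })
  ci <- 1.96 * sqrt(0.05 * 0.95 / 300)
  expect_lt(abs(mean(rej) - 0.05), ci + 0.01)
})

test_that("post-hoc differences match exact two-group enumeration", {
  withr::local_seed(5)
  y <- c(rnorm(4), rnorm(4, mean = 1.5))
  fac <- data.frame(g = rep(c("lo", "hi"), each = 4))
  ph <- perm_posthoc(y, fac, "g", stats_config(n_permutations = 4000,
                                               seed = 6))
  d_obs <- mean(y[fac$g == ph$cell_a[1]]) - mean(y[fac$g == ph$cell_b[1]])
  expect_equal(ph$difference[1], d_obs)
  combos <- utils::combn(8, 4)
  d_all <- apply(combos, 2, function(idx) mean(y[idx]) - mean(y[-idx]))
  p_exact <- mean(abs(d_all) >= abs(d_obs) - 1e-12)
  expect_lt(abs(ph$p_mc[1] - p_exact), 0.02)

  same <- perm_posthoc(rep(y[1:4], 2), fac, "g", cfg_fast)
  expect_equal(same$difference[1], 0)
  expect_gt(same$p_mc[1], 0.9)
  expect_error(perm_posthoc(1:3, data.frame(g = c("a", "a", "b")), "g",
                            cfg_fast), "fewer than 2")
})

test_that("BH step-up matches the hand formula and p.adjust", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_equal(r$adjusted, rep(0.04, 4))
  expect_true(all(r$rejected))

  expect_equal(fdr_bh(0.03)$adjusted, 0.03)   # single p unchanged
  expect_false(any(fdr_bh(rep(1, 5))$rejected))

  withr::local_seed(7)
  for (i in 1:10) {
    p <- runif(20)^2
    r2 <- fdr_bh(p)
    expect_equal(r2$adjusted, stats::p.adjust(p, "BH"))
    expect_true(all(r2$adjusted >= p - 1e-12))
    # never rejects more than raw alpha-thresholding
    expect_lte(sum(r2$rejected), sum(p <= 0.05))
  }
  expect_error(fdr_bh(numeric()), "empty")
})

test_that("cluster correction flags long runs and ignores isolated hits", {
  cfg <- stats_config(n_permutations = 2000, seed = 8)
  # a dense run among non-significant windows: the shuffled null almost
  # never reassembles 25 consecutive hits (note an entirely significant
  # series is shuffle-invariant, so the binarized-shuffle null can never
  # flag it -- contiguity against a sparse background is what the
  # correction rewards)
  p25 <- c(rep(0.5, 8), rep(0.01, 25), rep(0.5, 7))
  dense <- cluster_mcs(p25, cfg)
  expect_equal(nrow(dense$clusters), 1L)
  expect_equal(dense$clusters$size, 25L)
  expect_true(dense$clusters$significant)

  none <- cluster_mcs(runif(40, 0.06, 1), cfg)
  expect_equal(nrow(none$clusters), 0L)

  # 116 windows: a 30-long run among independent uniforms, plus one
  # isolated significant window
  withr::local_seed(9)
  p <- runif(116, 0.051, 1)
  p[40:69] <- 0.01
  p[5] <- 0.01
  r <- cluster_mcs(p, cfg)
  sig <- r$clusters[r$clusters$significant, ]
  expect_equal(nrow(sig), 1L)
  expect_equal(c(sig$start, sig$end), c(40, 69))
  expect_error(cluster_mcs(0.01, cfg), "shorter")
})

test_that("exact Spearman reproduces the printed n = 6 configuration", {
  r <- perm_spearman(1:6, c(5, 6, 4, 3, 1, 2))
  expect_equal(round(r$rho, 2), -0.89)
  expect_equal(r$rho, cor(1:6, c(5, 6, 4, 3, 1, 2), method = "spearman"))
  expect_true(r$exact)
  expect_equal(r$p, 24 / 720)
  expect_equal(round(r$p, 3), 0.033)

  ident <- perm_spearman(1:6, 1:6)
  expect_equal(ident$rho, 1)
  expect_equal(ident$p, 2 / 720)
  expect_error(perm_spearman(1:6, rep(1, 6)), "constant")
})

test_that("Monte-Carlo Spearman converges to the exact enumeration", {
  withr::local_seed(10)
  x <- rnorm(7); y <- x + rnorm(7, sd = 1.5)
  p_exact <- perm_spearman(x, y)$p
  p_mc <- perm_spearman(x, y, stats_config(n_permutations = 4000, seed = 1),
                        exact_n_max = 3)$p
  expect_false(perm_spearman(x, y, exact_n_max = 3)$exact)
  expect_lt(abs(p_mc - p_exact), 0.02)
})

test_that("trend regression satisfies its algebraic identities", {
  cfg <- stats_config(n_permutations = 500, seed = 11)
  t <- seq(0, 1, length.out = 50)
  perfect <- linreg_trend(t, 2 - 3 * t, cfg)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$r2_adjusted, 1)
  expect_equal(perfect$slope, -3)
  expect_equal(perfect$df, c(1, 48))

  withr::local_seed(12)
  null <- linreg_trend(seq_len(500), rnorm(500), cfg)
  expect_lt(abs(null$r2_adjusted), 0.02)

  for (i in 1:10) {
    v <- rnorm(30); tt <- rnorm(30)
    r <- linreg_trend(tt, v, cfg)
    expect_equal(r$r2, r$F / (r$F + r$df[2]))      # R^2 = F/(F+df2)
    ref <- stats::lm(v ~ tt)
    expect_equal(r$slope, unname(coef(ref)[2]))
    expect_equal(r$r2_adjusted, summary(ref)$adj.r.squared)
    expect_equal(r$F, unname(summary(ref)$fstatistic[1]))
  }
  expect_error(linreg_trend(rep(1, 5), rnorm(5), cfg), "constant")
})

test_that("permutation p-values are uniform under the null", {
  withr::local_seed(13)
  ps <- replicate(400, {
    x <- rnorm(10); y <- rnorm(10)
    perm_ttest_paired(x, y, stats_config(n_permutations = 200))$p_mc
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the normality gate reports without branching the inference", {
  withr::local_seed(14)
  g <- shapiro_gate(rnorm(50))
  expect_true(g$normal)
  expect_true(g$W > 0.9)
  skewed <- shapiro_gate(rexp(50)^2)
  expect_false(skewed$normal)
})

test_that("seeded results are reproducible", {
  x <- rnorm(8); y <- rnorm(8)
  a <- perm_ttest_paired(x, y, stats_config(n_permutations = 300, seed = 5))
  b <- perm_ttest_paired(x, y, stats_config(n_permutations = 300, seed = 5))
  expect_identical(a$p_mc, b$p_mc)
  expect_equal(a$seed, 5)
})
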