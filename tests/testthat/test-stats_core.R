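# Statistical toolbox: H-score, t test, Mann-Whitney, ANOVA, BH, Fisher/EASE.

test_that("H-score is the product of percent positive and intensity", {
  expect_equal(ihc_score(100, 3), 300)
  expect_equal(ihc_score(50, 2), 100)
  expect_equal(ihc_score(c(10, 80), 0), c(0, 0))
  expect_error(ihc_score(101, 2), "percent")
  expect_error(ihc_score(50, 4), "intensity")
  expect_error(ihc_score(50, 1.5), "intensity")
})

test_that("t test matches the closed-form pooled oracle and stats::t.test", {
  mine <- t_test_two_tailed(c(1, 2, 3), c(2, 3, 4), equal_variance = TRUE)
  # pooled oracle by hand: means 2 and 3, both variances 1, sp2 = 1,
  # se = sqrt(2/3), t = -1/se, df = 4
  t_hand <- -1 / sqrt(2 / 3)
  expect_scalar_equal(mine$statistic, t_hand)
  expect_scalar_equal(mine$p_value, 2 * pt(t_hand, 4))
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(7); b <- rnorm(9, 0.5, 2)
    for (eq in c(TRUE, FALSE)) {
      m <- t_test_two_tailed(a, b, equal_variance = eq)
      o <- t.test(a, b, var.equal = eq)
      expect_equal(m$statistic, unname(o$statistic), tolerance = 1e-12)
      expect_equal(m$p_value, o$p.value, tolerance = 1e-12)
      expect_equal(m$df, unname(o$parameter), tolerance = 1e-9)
    }
  }
})

test_that("t test: identical groups, antisymmetry, degenerate variance", {
  same <- t_test_two_tailed(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  ab <- t_test_two_tailed(c(1, 5, 2), c(4, 4, 7))
  ba <- t_test_two_tailed(c(4, 4, 7), c(1, 5, 2))
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  flat_eq <- t_test_two_tailed(c(2, 2), c(2, 2))
  expect_true(flat_eq$degenerate)
  expect_equal(flat_eq$p_value, 1)
  flat_ne <- t_test_two_tailed(c(2, 2), c(3, 3))
  expect_true(flat_ne$degenerate)
  expect_equal(flat_ne$p_value, 0)
})

test_that("Mann-Whitney exact enumeration and conventions", {
  m <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m$statistic, 0)
  expect_equal(m$p_value, 0.1)  # 2 of C(6,3)=20 extreme arrangements
  expect_true(m$exact)
  # identical groups (ties -> approximation route): p = 1
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  # label swap: p unchanged, U -> n_a n_b - U
  a <- c(0.3, 1.9, 2.2, 5.1); b <- c(0.7, 3.3, 4.4)
  ab <- mann_whitney_u(a, b); ba <- mann_whitney_u(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$statistic, length(a) * length(b) - ba$statistic)
  # exact route agrees with wilcox.test exact p
  for (seed in 1:5) {
    set.seed(seed)
    x <- sample(seq(1, 100), 5); y <- sample(seq(101, 200), 6) / 7
    m <- mann_whitney_u(x, y)
    o <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    expect_equal(m$p_value, o$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact and normal approximation agree within the
           enumerated worst-case bound at n = 6 + 6", {
  # Enumerating all C(12,6) rank assignments shows the largest possible
  # |exact - approx| under the doubling convention is ~0.069 (attained at
  # U = 16, in the centre of the null distribution, a discreteness
  # artifact); the approximation cannot be uniformly closer than that.
  mw_exact <- stratsurv:::mw_exact_p
  mw_approx <- stratsurv:::mw_approx_p
  set.seed(11)
  for (rep in 1:10) {
    a <- rnorm(6); b <- rnorm(6, 0.5)
    r <- rank(c(a, b))
    u <- sum(r[1:6]) - 6 * 7 / 2
    p_ex <- mw_exact(u, 6, 6)
    p_ap <- mw_approx(u, 6, 6, c(a, b))$p
    expect_lt(abs(p_ex - p_ap), 0.07)
  }
})

test_that("one-way ANOVA: hand example, equal means, permutation invariance", {
  r <- one_way_anova(list(c(1, 2), c(2, 3)))
  expect_scalar_equal(r$statistic, 2)          # SSB = 1, SSW = 1, df (1, 2)
  expect_scalar_equal(r$p_value, 1 - sqrt(2) / 2)
  eq <- one_way_anova(list(c(1, 3), c(0, 4), c(2, 2)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  set.seed(2)
  gs <- list(rnorm(5), rnorm(6, 1), rnorm(4, 2))
  expect_equal(one_way_anova(gs)$statistic,
               one_way_anova(rev(gs))$statistic)
  # oracle: stats::oneway.test with equal variances
  o <- oneway.test(y ~ g, data.frame(y = unlist(gs),
                                     g = rep(1:3, lengths(gs))),
                   var.equal = TRUE)
  expect_equal(one_way_anova(gs)$statistic, unname(o$statistic),
               tolerance = 1e-12)
})

test_that("F = t^2 on two-group equal-variance inputs", {
  set.seed(4)
  for (rep in 1:5) {
    a <- rnorm(6); b <- rnorm(8, 0.7)
    tt <- t_test_two_tailed(a, b, equal_variance = TRUE)
    ff <- one_way_anova(list(a, b))
    expect_equal(ff$statistic, tt$statistic^2, tolerance = 1e-10)
    expect_equal(ff$p_value, tt$p_value, tolerance = 1e-10)
  }
})

test_that("two-way ANOVA: reduction, scale invariance, balanced oracle", {
  set.seed(7)
  y <- rnorm(12)
  fa <- rep(c("x", "y", "z"), each = 4)
  fb <- rep(c("u", "v"), 6)
  # constant factor_b collapses to the one-way layout
  red <- two_way_anova(y, fa, rep("c", 12))
  one <- one_way_anova(split(y, fa))
  expect_equal(red$factor_a$statistic, one$statistic)
  expect_equal(red$factor_a$p_value, one$p_value)
  expect_true(red$factor_b$degenerate)
  # scaling the response leaves F unchanged
  full <- two_way_anova(y, fa, fb)
  scaled <- two_way_anova(10 * y, fa, fb)
  expect_equal(full$factor_a$statistic, scaled$factor_a$statistic,
               tolerance = 1e-10)
  expect_equal(full$factor_b$statistic, scaled$factor_b$statistic,
               tolerance = 1e-10)
  # balanced design: type-II equals sequential ANOVA from stats::lm
  o <- anova(lm(y ~ factor(fa) + factor(fb)))
  expect_equal(full$factor_a$statistic, o[["F value"]][1], tolerance = 1e-9)
  expect_equal(full$factor_b$statistic, o[["F value"]][2], tolerance = 1e-9)
  expect_equal(full$factor_b$p_value, o[["Pr(>F)"]][2], tolerance = 1e-9)
  expect_error(two_way_anova(y, rep("a", 12), rep("b", 12)), "levels")
})

test_that("two-way ANOVA null simulation rejects at about the 5% level", {
  set.seed(21)
  rej <- replicate(400, {
    y <- rnorm(18)
    fa <- sample(rep(c("a", "b", "c"), 6))
    fb <- sample(rep(c("u", "v"), 9))
    two_way_anova(y, fa, fb)$factor_a$p_value < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("BH adjustment: worked example, edge cases, oracle, monotonicity", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (rep in 1:5) {
    p <- runif(200)^2
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-14)
    expect_true(all(q <= 1) && all(q >= p))
    # adjusted values preserve the ordering of the raw p-values
    expect_true(all(diff(q[order(p)]) >= 0))
  }
  # idempotence holds on constant vectors (the general claim is false:
  # re-adjusting re-applies the m/i scaling)
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
})

test_that("Fisher/EASE enrichment: hand table, oracle, conservativeness", {
  f <- fisher_enrichment(10, 5, 4, 4)
  expect_scalar_equal(f$p_value, 5 / 210)     # C(5,4)C(5,0)/C(10,4)
  expect_equal(f$fold_enrichment, 2)
  e <- fisher_enrichment(10, 5, 4, 4, ease = TRUE)
  expect_scalar_equal(e$p_value, 55 / 210)    # P(X = 3) + P(X = 4)
  expect_equal(fisher_enrichment(10, 5, 4, 1, ease = TRUE)$p_value, 1)
  expect_equal(fisher_enrichment(10, 5, 4, 0)$p_value, 1)
  expect_error(fisher_enrichment(10, 5, 4, 5), "inadmissible")
  expect_error(fisher_enrichment(10, 5, 0, 0), "positive")
  # against fisher.test one-sided, and EASE >= Fisher everywhere
  set.seed(17)
  for (rep in 1:20) {
    N <- sample(20:60, 1); K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(max(0, n + K - N):min(K, n), 1)  # admissible overlap only
    fe <- fisher_enrichment(N, K, n, k)
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    expect_equal(fe$p_value,
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
    expect_gte(fisher_enrichment(N, K, n, k, ease = TRUE)$p_value,
               fe$p_value)
  }
})

test_that("boxplot summary follows the median +/- 1.5 IQR convention", {
  s <- boxplot_summary(c(1, 2, 3, 4, 5))
  expect_equal(unname(s["median"]), 3)
  expect_equal(unname(s["iqr"]), 2)
  expect_equal(unname(s["whisker_low"]), 0)
  expect_equal(unname(s["whisker_high"]), 6)
})
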