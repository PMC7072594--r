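# Kaplan-Meier, weighted log-rank and univariate Cox against hand
# computations and the survival package used as an independent oracle.

test_that("KM estimate matches hand product-limit values", {
  km <- km_estimate(km3_records())
  expect_equal(km$table$time, c(1, 3))
  expect_equal(km$table$n_risk, c(3, 1))
  expect_equal(km$table$survival, c(2 / 3, 0))
  # all censored: survival stays at 1 (no event rows at all)
  none <- km_estimate(data.frame(time = c(2, 5), event = c(0, 0)))
  expect_equal(nrow(none$table), 0)
  expect_equal(risk_table(none, 0), 2)
  expect_error(km_estimate(data.frame(time = numeric(0),
                                      event = integer(0))), "empty")
})

test_that("KM equals the empirical survival function without censoring,
           and is invariant under record duplication", {
  set.seed(31)
  tm <- rexp(40, 0.3)
  km <- km_estimate(data.frame(time = tm, event = 1))
  emp <- vapply(km$table$time, function(t) mean(tm > t), numeric(1))
  expect_equal(km$table$survival, emp, tolerance = 1e-12)
  rec <- random_survival(32)
  km1 <- km_estimate(rec)
  km2 <- km_estimate(rbind(rec, rec))
  expect_equal(km1$table$survival, km2$table$survival, tolerance = 1e-12)
})

test_that("KM and risk table agree with survival::survfit", {
  skip_if_not_installed("survival")
  for (seed in 1:4) {
    rec <- random_survival(seed, n = 60)
    km <- km_estimate(rec)
    fit <- survival::survfit(survival::Surv(rec$time, rec$event) ~ 1)
    s <- summary(fit, times = km$table$time)
    expect_equal(km$table$survival, s$surv, tolerance = 1e-12)
    expect_equal(risk_table(km, km$table$time), s$n.risk)
  }
})

test_that("risk table boundary behaviour and monotonicity", {
  km <- km_estimate(random_survival(33))
  expect_equal(risk_table(km, 0), km$n)
  expect_equal(risk_table(km, max(km$obs_time) + 1), 0)
  ts <- seq(0, max(km$obs_time), length.out = 10)
  expect_true(all(diff(risk_table(km, ts)) <= 0))
  expect_error(risk_table(km, -1), "non-negative")
})

test_that("log-rank matches the 4-subject hand computation", {
  g <- four_subject_groups()
  mh <- logrank_test(g$g1, g$g2)
  expect_scalar_equal(mh$statistic, 49 / 17)
  expect_scalar_equal(mh$p_value, pchisq(49 / 17, 1, lower.tail = FALSE))
  expect_equal(sum(mh$observed - mh$expected), 0, tolerance = 1e-12)
  gw <- logrank_test(g$g1, g$g2, "gehan-wilcoxon")
  expect_scalar_equal(gw$statistic, 16 / 6)
})

test_that("log-rank degenerate and symmetry properties", {
  a <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1))
  same <- logrank_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  no_events <- logrank_test(data.frame(time = 1:3, event = 0),
                            data.frame(time = 1:3, event = 0))
  expect_true(no_events$degenerate)
  expect_equal(no_events$p_value, 1)
  for (seed in 5:8) {
    r1 <- random_survival(seed); r2 <- random_survival(seed + 100, n = 30)
    ab <- logrank_test(r1, r2); ba <- logrank_test(r2, r1)
    expect_equal(ab$statistic, ba$statistic, tolerance = 1e-12)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  }
})

test_that("both weightings agree with survival::survdiff", {
  skip_if_not_installed("survival")
  for (seed in 1:6) {
    r1 <- random_survival(seed, 40); r2 <- random_survival(seed + 50, 35)
    tm <- c(r1$time, r2$time); ev <- c(r1$event, r2$event)
    gp <- rep(1:2, c(40, 35))
    mh <- logrank_test(r1, r2)
    sd0 <- survival::survdiff(survival::Surv(tm, ev) ~ gp, rho = 0)
    expect_equal(mh$statistic, sd0$chisq, tolerance = 1e-9)
    expect_equal(mh$observed, unname(sd0$obs), tolerance = 1e-9)
    expect_equal(mh$expected, unname(sd0$exp), tolerance = 1e-9)
  }
  # Gehan-Wilcoxon vs Mantel-Haenszel: identical with a single event time
  one_t <- logrank_test(data.frame(time = c(5, 5, 9), event = c(1, 1, 0)),
                        data.frame(time = c(5, 8), event = c(1, 0)))
  one_g <- logrank_test(data.frame(time = c(5, 5, 9), event = c(1, 1, 0)),
                        data.frame(time = c(5, 8), event = c(1, 0)),
                        "gehan-wilcoxon")
  expect_equal(one_t$statistic, one_g$statistic, tolerance = 1e-12)
})

test_that("Cox fit maximizes the Breslow partial likelihood (grid oracle)", {
  rec <- data.frame(time = c(3, 5, 7, 2, 18, 11, 8, 1, 6, 9),
                    event = c(1, 0, 1, 1, 0, 1, 1, 1, 0, 1))
  x <- c(0.5, -1.2, 0.3, 2.0, -0.7, 1.1, 0.0, 1.8, -0.4, 0.9)
  fit <- cox_univariate(x, rec)
  derivs <- stratsurv:::cox_derivs
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, function(b) derivs(b, x, rec$time, rec$event)$loglik,
               numeric(1))
  expect_lt(abs(fit$beta - grid[which.max(ll)]), 1e-4 + 1e-8)
  expect_true(fit$converged)
  expect_true(fit$ci_low < fit$hr && fit$hr < fit$ci_high)
})

test_that("Cox agrees with survival::coxph (Breslow ties)", {
  skip_if_not_installed("survival")
  for (seed in 1:5) {
    set.seed(seed)
    n <- 80
    x <- rnorm(n)
    tm <- rexp(n, 0.1 * exp(0.6 * x))
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) next
    mine <- cox_univariate(x, data.frame(time = tm, event = ev))
    orc <- survival::coxph(survival::Surv(tm, ev) ~ x, ties = "breslow")
    expect_equal(mine$beta, unname(coef(orc)), tolerance = 1e-7)
    expect_equal(mine$se, sqrt(unname(vcov(orc)[1, 1])), tolerance = 1e-7)
  }
})

test_that("Cox score test at beta = 0 equals the Mantel-Haenszel chi-square
           for a binary covariate without cross-group event-time ties", {
  set.seed(41)
  tm <- sample(1:1000, 50)
  ev <- rbinom(50, 1, 0.7)
  gp <- rbinom(50, 1, 0.4)
  fit <- cox_univariate(as.numeric(gp), data.frame(time = tm, event = ev))
  lr <- logrank_test(data.frame(time = tm[gp == 1], event = ev[gp == 1]),
                     data.frame(time = tm[gp == 0], event = ev[gp == 0]))
  expect_equal(fit$score_statistic, lr$statistic, tolerance = 1e-10)
})

test_that("Cox reparameterization and input validation", {
  rec <- random_survival(43, 40)
  x <- rnorm(40)
  f1 <- cox_univariate(x, rec)
  f2 <- cox_univariate(-x, rec)
  expect_equal(f1$beta, -f2$beta, tolerance = 1e-7)
  expect_equal(f1$hr, 1 / f2$hr, tolerance = 1e-6)
  expect_error(cox_univariate(rep(1, 40), rec), "constant")
  expect_error(cox_univariate(x, data.frame(time = rec$time, event = 0)),
               "event")
})

test_that("Cox recovers the true log hazard ratio on simulated cohorts", {
  betas <- vapply(1:25, function(seed) {
    st <- quick_study(seed + 700, n = 500, hr = 2, n_genes = 2,
                      censoring_rate = 0.04)
    cov <- as.numeric(st$truth$hi)
    cox_univariate(cov, st$clinical)$beta
  }, numeric(1))
  expect_lt(abs(mean(betas) - log(2)), 0.15)
})
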