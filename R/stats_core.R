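# Core statistical toolbox: two-sample tests, ANOVA, BH adjustment,
# hypergeometric/EASE enrichment, IHC H-score.  All tests return a
# "stratsurv_test" object so downstream code can treat them uniformly.

new_test_result <- function(statistic, p_value, df = NA_real_, method = "",
                            degenerate = FALSE, extra = list()) {
  structure(c(list(statistic = statistic, p_value = p_value, df = df,
                   method = method, degenerate = degenerate), extra),
            class = "stratsurv_test")
}

#' @export
print.stratsurv_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic),
      ", df = ", format(x$df),
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  if (isTRUE(x$degenerate)) cat("  (degenerate input)\n")
  invisible(x)
}

#' Immunohistochemistry H-score
#'
#' Scores a stained tissue core by multiplying the percentage of positive
#' cells with the staining intensity (no staining: 0, weak: 1, medium: 2,
#' strong: 3), giving a score in \[0, 300\].
#'
#' @param percent_positive Percentage of positively stained cells, in
#'   \[0, 100\]. Vectorized.
#' @param intensity Integer staining intensity in \{0, 1, 2, 3\}. Vectorized.
#' @return Numeric vector of H-scores in \[0, 300\].
#' @examples
#' ihc_score(50, 2)   # 100
#' ihc_score(100, 3)  # 300
#' @export
ihc_score <- function(percent_positive, intensity) {
  if (!is.numeric(percent_positive) || any(!is.finite(percent_positive)) ||
      any(percent_positive < 0) || any(percent_positive > 100))
    stop("percent_positive must be in [0, 100]")
  if (!is.numeric(intensity) || any(!is.finite(intensity)) ||
      any(intensity != round(intensity)) || any(!(intensity %in% 0:3)))
    stop("intensity must be an integer in {0, 1, 2, 3}")
  percent_positive * intensity
}

check_group <- function(x, name, min_n = 2L) {
  if (!is.numeric(x) || length(x) < min_n || any(!is.finite(x)))
    stop(sprintf("%s must be a numeric vector of >= %d finite values",
                 name, min_n))
  invisible(x)
}

#' Two-tailed two-sample t test
#'
#' Welch's unequal-variance t test by default; `equal_variance = TRUE`
#' selects the pooled-variance Student test. The sign of the statistic
#' follows `mean(group_a) - mean(group_b)`.
#'
#' Degenerate inputs (zero variance in both groups) are flagged: p = 1 when
#' the means agree, p = 0 when they differ.
#'
#' @param group_a,group_b Numeric vectors, each with at least two values.
#' @param equal_variance Pool the variances (classic Student t)?
#' @return A `stratsurv_test` with fields `statistic`, `p_value`, `df`.
#' @export
t_test_two_tailed <- function(group_a, group_b, equal_variance = FALSE) {
  check_group(group_a, "group_a"); check_group(group_b, "group_b")
  na <- length(group_a); nb <- length(group_b)
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  method <- if (equal_variance) "two-tailed t test (pooled)" else
    "two-tailed t test (Welch)"
  if (va == 0 && vb == 0) {
    return(new_test_result(statistic = if (ma == mb) 0 else Inf * sign(ma - mb),
                           p_value = if (ma == mb) 1 else 0,
                           method = method, degenerate = TRUE))
  }
  if (equal_variance) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se2a <- va / na; se2b <- vb / nb
    se <- sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  new_test_result(tstat, 2 * stats::pt(-abs(tstat), df), df = df,
                  method = method)
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
mw_exact_p <- function(u_obs, n_a, n_b) {
  cmb <- utils::combn(n_a + n_b, n_a)
  u_all <- colSums(cmb) - n_a * (n_a + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Normal approximation with tie correction (no continuity correction).
mw_approx_p <- function(u_obs, n_a, n_b, pooled_values) {
  n <- n_a + n_b
  mu <- n_a * n_b / 2
  tie_counts <- table(pooled_values)
  sigma2 <- n_a * n_b / 12 *
    ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(p = 1, degenerate = TRUE))
  list(p = 2 * stats::pnorm(-abs((u_obs - mu) / sqrt(sigma2))),
       degenerate = FALSE)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small samples (`n_a + n_b <= 12`) without
#' ties the p-value is exact, by enumeration of all rank assignments with the
#' doubling convention `min(1, 2 * one-sided)`; otherwise a tie-corrected
#' normal approximation is used. The reported U is the statistic for
#' `group_a`.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A `stratsurv_test`; `statistic` is U for `group_a`, the `exact`
#'   field records which route was taken.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  check_group(group_a, "group_a", 1L); check_group(group_b, "group_b", 1L)
  na <- length(group_a); nb <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (na + nb <= 12 && !ties) {
    p <- mw_exact_p(u, na, nb)
    return(new_test_result(u, p, method = "Mann-Whitney U (exact)",
                           extra = list(exact = TRUE)))
  }
  ap <- mw_approx_p(u, na, nb, pooled)
  new_test_result(u, ap$p, method = "Mann-Whitney U (normal approximation)",
                  degenerate = ap$degenerate, extra = list(exact = FALSE))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects ANOVA: `F = MS_between / MS_within`, p from the
#' F distribution with (k - 1, n - k) degrees of freedom.
#'
#' @param groups A list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return A `stratsurv_test` with `df` of length two.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("groups must be a list of >= 2 numeric vectors")
  for (g in groups) check_group(g, "each group")
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  m <- vapply(groups, mean, numeric(1))
  grand <- sum(n * m) / sum(n)
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- sum(n) - k
  if (ssw == 0) {
    return(new_test_result(if (ssb == 0) 0 else Inf,
                           p_value = if (ssb == 0) 1 else 0,
                           df = c(df1, df2), method = "one-way ANOVA",
                           degenerate = TRUE))
  }
  fstat <- (ssb / df1) / (ssw / df2)
  new_test_result(fstat, stats::pf(fstat, df1, df2, lower.tail = FALSE),
                  df = c(df1, df2), method = "one-way ANOVA")
}

#' Two-way analysis of variance (main effects, type-II sums of squares)
#'
#' Fits the additive two-factor linear model and reports, for each factor,
#' the type-II F test: the extra sum of squares explained by that factor
#' after the other, against the residual of the additive model. If one
#' factor is constant the design collapses to a one-way layout: the constant
#' factor's effect is reported as degenerate and the other factor's test
#' equals [one_way_anova()].
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factors (or coercible) of the same length.
#' @return A list with elements `factor_a` and `factor_b`, each a
#'   `stratsurv_test`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  check_group(values, "values", 3L)
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (length(fa) != length(values) || length(fb) != length(values))
    stop("factors must match the length of values")
  if (nlevels(fa) < 2 && nlevels(fb) < 2)
    stop("at least one factor must have >= 2 levels")
  one_level <- function(f) nlevels(f) < 2
  degen <- new_test_result(NA_real_, NA_real_, method = "two-way ANOVA",
                           degenerate = TRUE)
  if (one_level(fb)) {
    res <- one_way_anova(split(values, fa))
    res$method <- "two-way ANOVA (factor_b constant; one-way reduction)"
    return(list(factor_a = res, factor_b = degen))
  }
  if (one_level(fa)) {
    res <- one_way_anova(split(values, fb))
    res$method <- "two-way ANOVA (factor_a constant; one-way reduction)"
    return(list(factor_a = degen, factor_b = res))
  }
  rss <- function(X) {
    fit <- stats::lm.fit(X, values)
    list(rss = sum(fit$residuals^2), rank = fit$rank)
  }
  full <- rss(stats::model.matrix(~ fa + fb))
  only_a <- rss(stats::model.matrix(~ fa))
  only_b <- rss(stats::model.matrix(~ fb))
  df_resid <- length(values) - full$rank
  if (df_resid < 1) stop("no residual degrees of freedom in additive model")
  ms_resid <- full$rss / df_resid
  effect <- function(reduced, label) {
    df_eff <- full$rank - reduced$rank
    ss <- reduced$rss - full$rss
    if (ms_resid == 0)
      return(new_test_result(if (ss <= 0) 0 else Inf,
                             p_value = if (ss <= 0) 1 else 0,
                             df = c(df_eff, df_resid),
                             method = paste("two-way ANOVA:", label),
                             degenerate = TRUE))
    fstat <- (ss / df_eff) / ms_resid
    new_test_result(fstat, stats::pf(fstat, df_eff, df_resid,
                                     lower.tail = FALSE),
                    df = c(df_eff, df_resid),
                    method = paste("two-way ANOVA:", label))
  }
  list(factor_a = effect(only_b, "factor_a"),
       factor_b = effect(only_a, "factor_b"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort p ascending, compute
#' `p_i * m / i`, enforce monotonicity from the largest rank down, cap at 1.
#' Values are returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (`p_FDR`), same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
      any(p_values < 0) || any(p_values > 1))
    stop("p_values must all lie in [0, 1]")
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values)
  q <- p_values[o] * m / seq_len(m)
  q <- pmin(1, rev(cummin(rev(q))))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Fisher exact / EASE gene-set enrichment statistic
#'
#' One-tailed hypergeometric upper-tail test of the overlap `k` between a
#' gene list of size `n` and a term of size `K` in a universe of size `N`:
#' `p = P(X >= k)`. With `ease = TRUE` the overlap is reduced by one while
#' the margins stay fixed (`p_EASE = P(X >= k - 1)`; `k <= 1` gives
#' `p_EASE = 1`), the conservative variant popularized by DAVID. Fold
#' enrichment is `(k/n) / (K/N)`.
#'
#' @param N Universe size.
#' @param K Term (gene-set) size within the universe.
#' @param n Gene-list size.
#' @param k Overlap between list and term.
#' @param ease Use the EASE modification?
#' @return A `stratsurv_test` with extra field `fold_enrichment`; the
#'   `statistic` is the overlap count used for the tail probability.
#' @export
fisher_enrichment <- function(N, K, n, k, ease = FALSE) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(!is.finite(vals)) || any(vals != round(vals)) || any(vals < 0))
    stop("N, K, n, k must be non-negative integers")
  if (n == 0) stop("gene list size n must be positive")
  if (K > N || n > N || k > min(K, n))
    stop("inadmissible enrichment table: require k <= min(K, n), K <= N, n <= N")
  k_eff <- if (ease) k - 1 else k
  p <- if (k_eff <= 0) 1 else
    stats::phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (K == 0) NA_real_ else (k / n) / (K / N)
  new_test_result(k_eff, p,
                  method = if (ease) "EASE (Fisher exact, overlap - 1)"
                           else "Fisher exact (hypergeometric upper tail)",
                  extra = list(fold_enrichment = fold, ease = ease))
}

#' Boxplot summary (median with 1.5 IQR whiskers)
#'
#' Descriptive helper matching the plotting convention of the clinical
#' figures: box is the median with interquartile range, whiskers extend to
#' median +/- 1.5 IQR.
#'
#' @param x Numeric vector.
#' @return Named numeric vector: median, q1, q3, iqr, whisker_low,
#'   whisker_high.
#' @export
boxplot_summary <- function(x) {
  check_group(x, "x", 1L)
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- qs[3] - qs[1]
  c(median = qs[2], q1 = qs[1], q3 = qs[3], iqr = iqr,
    whisker_low = qs[2] - 1.5 * iqr, whisker_high = qs[2] + 1.5 * iqr)
}
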