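# Survival machinery implemented from first principles: product-limit
# estimator, weighted two-group log-rank tests (Mantel-Haenszel and
# Gehan-Wilcoxon), and univariate Cox partial-likelihood fitting with
# Breslow tie handling.

validate_survival <- function(time, event, what = "records") {
  if (length(time) < 1) stop("empty ", what)
  if (!is.numeric(time) || any(!is.finite(time)) || any(time <= 0))
    stop("follow-up times must be finite and > 0")
  if (any(!(event %in% c(0, 1))))
    stop("event indicator must be 0 (censored) or 1 (event)")
  invisible(NULL)
}

as_survival_df <- function(records) {
  if (is.data.frame(records)) {
    if (!all(c("time", "event") %in% names(records)))
      stop("survival records need 'time' and 'event' columns")
    df <- records
  } else if (is.list(records) && all(c("time", "event") %in% names(records))) {
    df <- data.frame(time = records$time, event = records$event)
  } else stop("records must be a data.frame with time and event")
  if (is.null(df$sample_id))
    df$sample_id <- sprintf("S%d", seq_len(nrow(df)))
  validate_survival(df$time, df$event)
  df
}

# Shared risk-table skeleton for the log-rank family.  Events precede
# censoring at tied times (the censored subject is still at risk for the
# event at its own time), which the ">=" at-risk definition encodes.
lr_prepare <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  nblocks <- length(ut)
  # r_i = number of distinct event times <= time_i; subject i is at risk
  # for blocks 1..r_i
  r <- findInterval(time, ut)
  # e_i = block of subject i's own event (0 if censored)
  e <- ifelse(event == 1, match(time, ut), 0L)
  n <- length(time)
  cnt <- tabulate(r + 1L, nbins = nblocks + 1L)  # cnt[j] = #{i : r_i = j-1}
  # n_risk_j = n - #{i : r_i < j} = n - cumsum(cnt)[j]
  n_risk <- n - cumsum(cnt)[seq_len(nblocks)]
  d <- tabulate(e, nbins = nblocks)
  list(ut = ut, nblocks = nblocks, r = r, e = e, n = n,
       n_risk = n_risk, d = d)
}

# Weighted log-rank given prepared skeleton and logical group-1 membership.
lr_stat <- function(prep, grp1, weighting = c("mantel-haenszel",
                                              "gehan-wilcoxon")) {
  weighting <- match.arg(weighting)
  if (prep$nblocks == 0)
    return(list(statistic = 0, p_value = 1, o_minus_e = 0, variance = 0,
                observed = c(0, 0), expected = c(0, 0), degenerate = TRUE))
  n1 <- sum(grp1)
  cnt1 <- tabulate(prep$r[grp1] + 1L, nbins = prep$nblocks + 1L)
  n1_risk <- n1 - cumsum(cnt1)[seq_len(prep$nblocks)]
  d1 <- tabulate(prep$e[grp1], nbins = prep$nblocks)
  d <- prep$d; nr <- prep$n_risk
  e1 <- d * n1_risk / nr
  v <- ifelse(nr > 1,
              d * (n1_risk / nr) * (1 - n1_risk / nr) * (nr - d) / (nr - 1),
              0)
  w <- if (weighting == "gehan-wilcoxon") nr else rep(1, prep$nblocks)
  num <- sum(w * (d1 - e1))
  den <- sum(w^2 * v)
  if (den <= 0)
    return(list(statistic = 0, p_value = 1, o_minus_e = num, variance = den,
                observed = c(sum(d1), sum(d) - sum(d1)),
                expected = c(sum(e1), sum(d) - sum(e1)),
                degenerate = TRUE))
  stat <- num^2 / den
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       o_minus_e = num, variance = den,
       observed = c(sum(d1), sum(d) - sum(d1)),
       expected = c(sum(e1), sum(d) - sum(e1)),
       degenerate = FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function from right-censored follow-up. Censoring
#' tied with an event time is processed after the event (the censored
#' subject counts as at risk at that time).
#'
#' @param records Data frame with columns `time` (> 0) and `event` (0/1),
#'   optionally `sample_id`.
#' @return A `stratsurv_km` object: data frame of distinct event times with
#'   `n_risk`, `n_event` and `survival` after each, plus the observation
#'   vectors used (for risk tables).
#' @export
km_estimate <- function(records) {
  df <- as_survival_df(records)
  prep <- lr_prepare(df$time, df$event)
  surv <- cumprod(1 - prep$d / prep$n_risk)
  structure(list(table = data.frame(time = prep$ut,
                                    n_risk = prep$n_risk,
                                    n_event = prep$d,
                                    survival = surv),
                 n = prep$n, obs_time = df$time, obs_event = df$event),
            class = "stratsurv_km")
}

#' @export
print.stratsurv_km <- function(x, ...) {
  cat("Kaplan-Meier estimate: n =", x$n, ", events =",
      sum(x$table$n_event), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Numbers at risk at requested times
#'
#' Returns the number of subjects at risk immediately before each requested
#' time, as printed under Kaplan-Meier plots.
#'
#' @param curve A `stratsurv_km` object.
#' @param times Non-negative numeric vector of time points.
#' @return Integer vector of at-risk counts.
#' @export
risk_table <- function(curve, times) {
  stopifnot(inherits(curve, "stratsurv_km"))
  if (any(times < 0)) stop("times must be non-negative")
  vapply(times, function(t) sum(curve$obs_time >= t), numeric(1))
}

#' Two-group weighted log-rank test
#'
#' At each distinct event time the observed minus expected events in group 1
#' and the hypergeometric variance are accumulated with weights 1
#' (Mantel-Haenszel) or the number at risk (Gehan-Wilcoxon); the statistic
#' `(sum w (O - E))^2 / sum w^2 V` is referred to chi-square with 1 df.
#'
#' @param group1,group2 Survival data frames (`time`, `event`); both
#'   non-empty.
#' @param weighting `"mantel-haenszel"` (default) or `"gehan-wilcoxon"`.
#' @return A `stratsurv_logrank` object with observed/expected per group,
#'   the weighted variance, chi-square statistic and p-value. With no events
#'   at all the result is degenerate with p = 1.
#' @export
logrank_test <- function(group1, group2,
                         weighting = c("mantel-haenszel", "gehan-wilcoxon")) {
  weighting <- match.arg(weighting)
  g1 <- as_survival_df(group1); g2 <- as_survival_df(group2)
  time <- c(g1$time, g2$time)
  event <- c(g1$event, g2$event)
  grp1 <- c(rep(TRUE, nrow(g1)), rep(FALSE, nrow(g2)))
  prep <- lr_prepare(time, event)
  res <- lr_stat(prep, grp1, weighting)
  structure(c(res, list(weighting = weighting,
                        n = c(nrow(g1), nrow(g2)))),
            class = "stratsurv_logrank")
}

#' @export
print.stratsurv_logrank <- function(x, ...) {
  cat("Log-rank test (", x$weighting, ")\n", sep = "")
  cat("  n =", paste(x$n, collapse = " / "),
      " observed =", paste(round(x$observed, 2), collapse = " / "),
      " expected =", paste(round(x$expected, 2), collapse = " / "), "\n")
  cat("  chi-square =", format(x$statistic), " p =",
      format.pval(x$p_value), "\n")
  invisible(x)
}

# Breslow partial-likelihood value, score and information at beta.
cox_derivs <- function(beta, x, time, event) {
  o <- order(-time)
  x <- x[o]; time <- time[o]; event <- event[o]
  w <- exp(beta * x)
  c0 <- cumsum(w); c1 <- cumsum(w * x); c2 <- cumsum(w * x^2)
  n <- length(time)
  last <- which(c(time[-1] != time[-n], TRUE))  # end of each tie block
  block <- rep(seq_along(last), diff(c(0L, last)))
  d <- as.numeric(rowsum(event, block))
  sx <- as.numeric(rowsum(event * x, block))
  keep <- d > 0
  s0 <- c0[last][keep]; s1 <- c1[last][keep]; s2 <- c2[last][keep]
  d <- d[keep]; sx <- sx[keep]
  list(loglik = sum(beta * sx - d * log(s0)),
       score = sum(sx - d * s1 / s0),
       info = sum(d * (s2 / s0 - (s1 / s0)^2)))
}

#' Univariate Cox proportional-hazards fit
#'
#' Maximizes the Breslow partial likelihood for a single covariate by
#' Newton-Raphson from beta = 0; the standard error comes from the observed
#' information and the reported p-value is the Wald test. Monotone
#' likelihood (separation) and non-convergence are flagged and leave the
#' confidence interval undefined.
#'
#' @param covariate Numeric covariate, one value per record; must vary.
#' @param records Survival data frame (`time`, `event`); >= 1 event.
#' @param conf_level Confidence level for the hazard-ratio interval.
#' @return A `stratsurv_cox` object: `beta`, `se`, `hr`, `ci_low`,
#'   `ci_high`, `p_value`, `score_statistic` (score test at beta = 0),
#'   `converged`, `flag`.
#' @export
cox_univariate <- function(covariate, records, conf_level = 0.95) {
  df <- as_survival_df(records)
  if (length(covariate) != nrow(df))
    stop("covariate length must match the number of records")
  if (!is.numeric(covariate) || any(!is.finite(covariate)))
    stop("covariate must be finite numeric")
  if (stats::var(covariate) == 0) stop("covariate is constant")
  if (sum(df$event) < 1) stop("at least one event is required")
  x <- covariate; time <- df$time; event <- df$event
  d0 <- cox_derivs(0, x, time, event)
  score_stat <- if (d0$info > 0) d0$score^2 / d0$info else 0
  beta <- 0; converged <- FALSE; flag <- "ok"
  for (it in seq_len(50)) {
    dv <- cox_derivs(beta, x, time, event)
    if (dv$info <= 1e-12) { flag <- "separation"; break }
    step <- dv$score / dv$info
    if (abs(step) > 5) step <- sign(step) * 5  # damp wild early steps
    beta <- beta + step
    if (abs(beta) > 20) { flag <- "separation"; break }
    if (abs(step) < 1e-9) { converged <- TRUE; break }
  }
  dv <- cox_derivs(beta, x, time, event)
  se <- if (dv$info > 0) 1 / sqrt(dv$info) else NA_real_
  if (!converged && flag == "ok") flag <- "non-convergence"
  ok <- converged && flag == "ok"
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(beta = beta, se = se, hr = exp(beta),
                 ci_low = if (ok) exp(beta - z * se) else NA_real_,
                 ci_high = if (ok) exp(beta + z * se) else NA_real_,
                 p_value = if (ok) 2 * stats::pnorm(-abs(beta / se))
                           else NA_real_,
                 loglik = dv$loglik, score_statistic = score_stat,
                 n = nrow(df), n_events = sum(event),
                 conf_level = conf_level,
                 iterations = it, converged = converged, flag = flag),
            class = "stratsurv_cox")
}

#' @export
print.stratsurv_cox <- function(x, ...) {
  cat("Univariate Cox fit (Breslow ties): n =", x$n, ", events =",
      x$n_events, "\n")
  cat(sprintf("  HR = %.4g (%.4g, %.4g), beta = %.4g, SE = %.4g, p = %s\n",
              x$hr, x$ci_low, x$ci_high, x$beta, x$se,
              format.pval(x$p_value)))
  if (x$flag != "ok") cat("  flag:", x$flag, "\n")
  invisible(x)
}
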