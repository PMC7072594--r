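---
title: "Methods: survival-optimal expression stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival-optimal expression stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratsurv)
```

## Scope and model

`stratsurv` implements the computational chain of a single-gene prognostic
study: a cohort of `n` patients with log2 expression of one index gene,
right-censored follow-up `(t_i, delta_i)`, and a genome-wide expression
matrix. The chain is (i) survival-optimal dichotomization of the index
gene, (ii) two-group survival testing, (iii) stratified differential
expression, (iv) cross-study intersection, (v) gene-set enrichment, plus
immunohistochemistry H-score utilities for tissue-level validation.

## The cutpoint search and its selection bias

Candidate thresholds are the midpoints between consecutive distinct
expression values — any threshold strictly between two observed values
induces the same split, so midpoints avoid boundary ambiguity for the
strict rule "hi means expression \> threshold" (and stored thresholds
therefore round-trip: re-applying the rule reproduces the labels exactly).
Candidates leaving either group below `ceiling(min_group_fraction * n)`
samples are discarded; the default `min_group_fraction = 0.1` admits the
heavily asymmetric splits seen in published cohorts (e.g. 64 vs 28) while
excluding degenerate ones. At every candidate the Mantel–Haenszel log-rank
chi-square is computed from a shared risk-table skeleton; the argmax wins,
with ties broken toward the threshold closest to the median expression (a
deterministic rule that prefers balanced splits among equal statistics).

A statistic maximized over thresholds is *maximally selected*: under the
null its naive chi-square p-value is strongly anti-conservative. The
package reports the naive p at the optimum (matching field practice) and
offers `selection_adjusted_p()`, which re-runs the full search on
permuted survival data and reports
`(1 + #{permuted maxima >= observed}) / (B + 1)`. Permuting survival
against expression is implemented as permuting the group labels against a
fixed risk-table skeleton — an algebraically identical but much cheaper
formulation. The acceptance suite verifies that the naive optimized p
rejects far too often under the null while the adjusted p is approximately
uniform.

## Survival machinery

The Kaplan–Meier estimator, weighted log-rank tests and univariate Cox
model are implemented from first principles (the `survival` package
appears only as an independent oracle in the test suite):

* **Tied event/censoring times**: events precede censoring — a subject
  censored at an event time is still at risk for that event. This is the
  standard convention; the source analysis does not state one.
* **Log-rank family**: at each distinct event time with `d` events, `n` at
  risk and `n1` at risk in group 1, the contribution is `d*n1/n` expected
  events and hypergeometric variance `d*(n1/n)*(1-n1/n)*(n-d)/(n-1)`;
  weights are 1 (Mantel–Haenszel) or `n` (Gehan–Wilcoxon). "Wilcoxon test"
  for survival is read as Gehan–Breslow weighting; Peto–Peto would be the
  main alternative and is not implemented.
* **Cox fit**: Newton–Raphson from `beta = 0` on the Breslow partial
  likelihood (Breslow chosen so the score test at zero reproduces the
  Mantel–Haenszel chi-square for a binary covariate, an identity the tests
  assert numerically). Steps are damped to `|step| <= 5`; `|beta| > 20` or
  vanishing information flags monotone likelihood (separation) and leaves
  the CI undefined. Convergence tolerance is `1e-9` on the step. CIs are
  Wald at 95%, matching the published reporting convention.

## Statistical toolbox choices

* **t test**: Welch by default — the source states only "two-tailed
  T tests"; Welch is the safer default and `equal_variance = TRUE`
  restores pooled Student for oracle comparisons. Zero variance in both
  groups is flagged degenerate (p = 1 for equal means, else 0).
* **Mann–Whitney**: exact two-sided p by full enumeration for
  `n_a + n_b <= 12` without ties, using the doubling convention
  `min(1, 2 * one-sided)`; otherwise a tie-corrected normal approximation
  without continuity correction. Enumeration at `n = 6 + 6` shows the two
  routes can differ by up to 0.069 in absolute p near the centre of the
  null distribution — a discreteness artifact no convention removes — so
  the property test bounds their disagreement at 0.07, not tighter.
* **Two-way ANOVA**: additive model, type-II main-effect F tests via
  nested least-squares fits. A constant factor degrades gracefully to the
  one-way layout for the other factor (reported degenerate for itself)
  rather than erroring, so the documented one-way reduction holds.
* **Benjamini–Hochberg**: classic step-up, returned in input order. Note
  BH is *not* idempotent (re-adjusting re-applies the `m/i` scaling);
  the tests assert oracle agreement, bounds and order preservation
  instead.
* **Fisher/EASE**: upper-tail hypergeometric `P(X >= k)`; EASE replaces
  `k` by `k - 1` with margins fixed (`k <= 1` gives p = 1), the simplest
  faithful reading of the "one gene removed" modification. EASE is
  provably conservative relative to Fisher, asserted property-style.
  Whether the original enrichment used EASE or classical Fisher is not
  documented beyond an axis label, so both sit behind the `ease` flag
  (default TRUE).

## Differential expression and intersection

Fold-regulation is defined from the log2 mean difference `d` as `2^d` for
`d >= 0` and `-2^(-d)` otherwise — a signed-reciprocal convention on
already-log-scale data; `|fold| >= 1` always, and the significance rule
uses strict inequalities (`p_FDR < alpha`, `|fold| > 1.25`) exactly as the
thresholds are worded. The intersection counts directions independently;
a gene meeting the `min_studies` rule in both directions is reported only
as a conflict, and any mixed-direction gene appears in the conflict table
with its counts. The study count is configurable (`min_studies = 2`
default) because the source is ambiguous between four and five cohorts.
The enrichment universe defaults to all genes measured in at least one
study, since the original "whole genome" universe is not recoverable.

## What the generator emulates — and what it does not

`simulate_study()` states this world:

* index gene `~ 10 + N(0, 1) + N(0, noise_sd)` log2 units (unit latent
  between-sample spread plus measurement noise);
* hazard switches at the `true_cutpoint_quantile` (default 0.6) of index
  expression: exponential event times at `baseline_event_rate` (0.1 per
  time unit) below, multiplied by `hazard_ratio_hi_vs_lo` (3) above —
  proportional hazards hold *exactly*, so Cox/log-rank recovery tests are
  clean;
* independent exponential censoring (rate 0.05) capped at an
  administrative horizon of 15 time units, emulating registry follow-up
  (roughly 25–35% censoring at the defaults);
* planted genes shifted by `+/- de_log2_effect` (1 log2 unit) in the high
  group over homoscedastic Gaussian noise (`noise_sd = 1`) — matching the
  use of t tests on normalized log2 data;
* an ordinal Gleason-like grade binned from a noisy latent score
  `grade_shift * expression + N(0, 1)`.

Not emulated: microarray platform effects, batch structure, competing
risks, heteroscedastic or heavy-tailed expression noise, probe-level
redundancy, realistic pathology. A green recovery test therefore
establishes correctness of the *algorithms under their own assumptions*,
not robustness to real-cohort artifacts; the published per-cohort numbers
(thresholds 12.56/8.26/8.70/−0.76/17.45, study-specific DE counts) are
not reproducible without the original data and are treated as
documentation, not targets.

## Numerical and degenerate-input choices

* Log-rank with no events: degenerate result, p = 1 (not an error) —
  a group comparison with nothing observed is uninformative, not invalid;
  an empty group, by contrast, is an error.
* Variance terms at risk-set size 1 are set to 0 (the `(n-d)/(n-1)`
  factor is otherwise undefined).
* `alpha = 0` is admitted in the pipeline config so the vacuous-threshold
  behaviour (zero significant genes, empty enrichment) is expressible.
* All generator randomness runs under an internally scoped seed and
  restores the caller's RNG state; identical config + seed gives
  byte-identical study objects and, through the pipeline, byte-identical
  output files (asserted by md5 in the acceptance suite).

## Known limitations

Single-covariate Cox only (no multivariable adjustment, time-varying
effects or proportionality diagnostics); no moderated-variance DE
(limma-style shrinkage would dominate at small n); enrichment treats gene
sets as flat lists with no ontology structure or redundancy pruning; the
permutation correction re-runs the full search `B` times and is the one
deliberately expensive operation in the package.
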