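# stratsurv

Expression-based survival stratification, differential expression and
gene-set enrichment for multi-cohort transcriptomic studies.

## The problem

A recurring design in cancer transcriptomics asks whether the expression of
one *index gene* (here the motivating case is CAND1, a regulator of
cullin-RING ubiquitin ligases, in prostate-cancer cohorts) separates
patients into prognostic groups. The analysis chain is:

1. **Cutpoint stratification.** For the index gene's log2 expression
   `x₁…xₙ` with right-censored follow-up `(tᵢ, δᵢ)`, evaluate every
   candidate threshold `c` (midpoints of consecutive distinct values,
   subject to a minimum group fraction) and keep the one maximizing the
   Mantel–Haenszel (log-rank) chi-square between `hi = {i : xᵢ > c}` and
   `lo`. Because the statistic is *maximally selected*, the naive p at the
   optimum is anti-conservative; a permutation-based selection-adjusted p
   is available.
2. **Survival testing.** Kaplan–Meier product-limit curves with risk
   tables, the Mantel–Haenszel and Gehan–Wilcoxon weighted log-rank tests
   (weights 1 and n-at-risk in `(Σw(O−E))²/Σw²V`), and a univariate Cox
   model fit by Newton–Raphson on the Breslow partial likelihood, reported
   as HR with 95% CI.
3. **Differential expression.** Per-gene two-tailed t tests hi vs lo,
   Benjamini–Hochberg FDR, and signed fold-regulation `2^d` (or `−2^(−d)`
   for `d < 0`) from the log2 mean difference `d`. Significance:
   `p_FDR < 0.05` and `|fold| > 1.25`, both strict.
4. **Cross-study intersection.** Genes significantly regulated in the same
   direction in ≥ 2 studies; direction conflicts are reported, never
   silently assigned.
5. **Enrichment.** Hypergeometric upper-tail (Fisher exact) test per gene
   set, by default the conservative EASE variant `p = P(X ≥ k−1)`, with
   fold enrichment `(k/n)/(K/N)`.
6. **IHC H-scores.** Percent positive cells × staining intensity (0–3),
   range 0–300, with class comparisons by two-tailed t test.

A seeded synthetic-data generator (`simulate_study()`) produces multi-study
inputs with a planted cutpoint, proportional-hazards effect, planted
up/down genes and exponential censoring, so every stage is testable without
downloading cohort data.

## Worked example

```r
library(stratsurv)
st  <- simulate_study(simulation_config(n_samples = 300, n_genes = 2000, seed = 11))
idx <- st$expression["CAND1", ]
cp  <- find_optimal_cutpoint(idx, st$clinical)
cp
#> Optimal expression cutpoint (mantel-haenszel log-rank)
#>   threshold = 10.21  (lo: n = 169, hi: n = 131)
#>   chi-square = 53.8, unadjusted p = 2.2195e-13
#>   candidates evaluated: 241

cox_univariate(idx, st$clinical)
#> Univariate Cox fit (Breslow ties): n = 300 , events = 214
#>   HR = 1.348 (1.225, 1.484), beta = 0.2989, SE = 0.04903, p = 1.0921e-09

de <- de_per_study(st$expression, cp$labels, drop_index = "CAND1")
sum(de$significant)
#> [1] 207
```

The generator planted its hazard switch at the 0.6 expression quantile
(threshold 10.35); the search recovered a threshold at the 0.56 quantile
(10.21). Of the 207 significant genes, 103 are called up and 104 down —
the generator planted 100 of each. The Cox HR of 1.35 is per log2 unit of
continuous index expression, not the hi-vs-lo group contrast.

An end-to-end run over several studies (cutpoint → survival tests → DE →
intersection → enrichment, with a JSON manifest) is one call:

```r
run_pipeline(pipeline_config(studies, index_gene = "CAND1",
                             gene_sets = "sets.gmt", out_dir = "out"))
```

or from the shell via the launcher in `inst/cli/`:
`stratsurv run --config run.conf` (subcommands: `simulate`, `cutpoint`,
`de`, `enrich`, `run`).

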