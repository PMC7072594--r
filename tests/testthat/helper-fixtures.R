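# Shared fixtures, built in code.

# 4-subject two-group survival fixture with hand-computed log-rank values:
# O - E = 7/6, V = 17/36, Mantel-Haenszel chi-square = 49/17;
# Gehan-Wilcoxon weighted sums U = 4, Var = 6, chi-square = 16/6.
four_subject_groups <- function() {
  list(g1 = data.frame(time = c(1, 2), event = c(1, 1)),
       g2 = data.frame(time = c(3, 4), event = c(1, 1)))
}

# 3-subject KM fixture: S(1) = 2/3, S(3) = 0.
km3_records <- function() data.frame(time = c(1, 2, 3), event = c(1, 0, 1))

# Small, fast synthetic study: survival structure intact, few genes.
quick_study <- function(seed, n = 100, hr = 3, q = 0.6, n_genes = 10,
                        up = 0, down = 0, ...) {
  simulate_study(simulation_config(
    n_samples = n, n_genes = n_genes, hazard_ratio_hi_vs_lo = hr,
    true_cutpoint_quantile = q, n_de_genes_up = up, n_de_genes_down = down,
    seed = seed, ...))
}

random_survival <- function(seed, n = 50, event_p = 0.6) {
  with_seed <- get("with_seed", asNamespace("stratsurv"))
  with_seed(seed, data.frame(time = stats::rexp(n, 0.2),
                             event = stats::rbinom(n, 1, event_p)))
}

# Writes two planted synthetic studies to disk and returns pipeline
# study entries pointing at them.
write_two_studies <- function(dir, seeds = c(101, 102), n = 80,
                              n_genes = 120, up = 15, down = 15) {
  for (i in seq_along(seeds)) {
    st <- quick_study(seeds[i], n = n, n_genes = n_genes, up = up,
                      down = down, de_log2_effect = 1.5)
    write_study(st, file.path(dir, LETTERS[i]))
  }
  lapply(seq_along(seeds), function(i)
    list(name = LETTERS[i],
         expression = file.path(dir, LETTERS[i], "expression.tsv"),
         clinical = file.path(dir, LETTERS[i], "clinical.tsv")))
}

expect_scalar_equal <- function(actual, expected, tol = 1e-10) {
  expect_true(is.finite(actual))
  expect_equal(actual, expected, tolerance = tol)
}
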