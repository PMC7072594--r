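# Synthetic multi-study generator.  Emulates the statistical structure the
# downstream analysis assumes: one index gene whose expression drives a
# proportional-hazards effect through a latent cutpoint, planted
# differentially expressed genes with fixed log2 effects, independent
# exponential censoring with an administrative horizon, and an ordinal
# grade associated with the index gene.  Everything is deterministic given
# the seed.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_study()]. Defaults
#' describe a mid-sized expression cohort: 300 samples, 2000 genes on the
#' log2 scale, an index gene splitting the cohort at its 0.6 quantile with
#' a hazard ratio of 3 for high expressers, exponential survival
#' (baseline rate 0.1 events per time unit) with independent exponential
#' censoring (rate 0.05) capped at a follow-up horizon of 15 time units,
#' and 100 up- plus 100 down-regulated genes shifted by 1 log2 unit.
#'
#' @param n_samples,n_genes Cohort and panel size (positive integers).
#' @param index_gene_name Name of the stratifying gene.
#' @param true_cutpoint_quantile Quantile of index expression at which the
#'   hazard changes, strictly inside (0, 1).
#' @param hazard_ratio_hi_vs_lo Hazard ratio of high vs low expressers (> 0).
#' @param baseline_event_rate Event hazard in the low group (> 0).
#' @param censoring_rate Rate of the independent exponential censoring (> 0).
#' @param followup_horizon Administrative censoring cap (time units).
#' @param n_de_genes_up,n_de_genes_down Numbers of planted regulated genes.
#' @param de_log2_effect Planted mean shift (log2 units, > 0).
#' @param noise_sd Residual gene-level standard deviation (log2 units, > 0).
#' @param grade_levels Ordered labels of the ordinal grade (Gleason-like).
#' @param grade_shift Association strength between index expression and
#'   grade (0 = independent).
#' @param seed Integer seed.
#' @return A validated `stratsurv_simconfig` list.
#' @export
simulation_config <- function(n_samples = 300, n_genes = 2000,
                              index_gene_name = "CAND1",
                              true_cutpoint_quantile = 0.6,
                              hazard_ratio_hi_vs_lo = 3,
                              baseline_event_rate = 0.1,
                              censoring_rate = 0.05,
                              followup_horizon = 15,
                              n_de_genes_up = 100, n_de_genes_down = 100,
                              de_log2_effect = 1, noise_sd = 1,
                              grade_levels = c("GS<=6", "GS=7", "GS>=8"),
                              grade_shift = 1, seed = 1) {
  cfg <- list(n_samples = n_samples, n_genes = n_genes,
              index_gene_name = index_gene_name,
              true_cutpoint_quantile = true_cutpoint_quantile,
              hazard_ratio_hi_vs_lo = hazard_ratio_hi_vs_lo,
              baseline_event_rate = baseline_event_rate,
              censoring_rate = censoring_rate,
              followup_horizon = followup_horizon,
              n_de_genes_up = n_de_genes_up,
              n_de_genes_down = n_de_genes_down,
              de_log2_effect = de_log2_effect, noise_sd = noise_sd,
              grade_levels = grade_levels, grade_shift = grade_shift,
              seed = seed)
  bad <- function(field, msg) stop(sprintf("invalid %s: %s", field, msg))
  pos_int <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
    x == round(x) && x > 0
  if (!pos_int(n_samples)) bad("n_samples", "must be a positive integer")
  if (!pos_int(n_genes) || n_genes < 2)
    bad("n_genes", "must be an integer >= 2")
  if (!is.character(index_gene_name) || nchar(index_gene_name) == 0)
    bad("index_gene_name", "must be a non-empty string")
  if (!is.numeric(true_cutpoint_quantile) ||
      true_cutpoint_quantile <= 0 || true_cutpoint_quantile >= 1)
    bad("true_cutpoint_quantile", "must lie strictly inside (0, 1)")
  for (f in c("hazard_ratio_hi_vs_lo", "baseline_event_rate",
              "censoring_rate", "de_log2_effect", "noise_sd",
              "followup_horizon")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      bad(f, "must be a positive real")
  }
  for (f in c("n_de_genes_up", "n_de_genes_down")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v != round(v) || v < 0)
      bad(f, "must be a non-negative integer")
  }
  if (n_de_genes_up + n_de_genes_down >= n_genes)
    bad("n_de_genes_up/n_de_genes_down",
        "planted genes must number fewer than n_genes")
  if (length(grade_levels) < 2) bad("grade_levels", "need >= 2 levels")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    bad("seed", "must be a single integer")
  structure(cfg, class = "stratsurv_simconfig")
}

#' Simulate one expression study with survival follow-up
#'
#' Index-gene expression is Gaussian around 10 log2 units with unit
#' between-sample spread plus `noise_sd` measurement noise. Samples above
#' the `true_cutpoint_quantile` quantile form the high-hazard group: their
#' event times are exponential with rate
#' `baseline_event_rate * hazard_ratio_hi_vs_lo`, the rest with the
#' baseline rate. Censoring is independent exponential capped at the
#' follow-up horizon; events occurring before the censoring time are
#' observed. Planted up/down genes have their mean shifted by
#' `+/- de_log2_effect` in the high group; all other genes are identically
#' distributed in both groups. Grade is derived from index expression via a
#' noisy latent score binned at its quantiles.
#'
#' @param config A `stratsurv_simconfig` from [simulation_config()].
#' @return A `stratsurv_study`: `expression` (genes x samples log2 matrix),
#'   `clinical` (sample_id, time, event, grade), and `truth` (planted
#'   threshold, quantile, hi labels, up/down gene ids, hazard ratio).
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "stratsurv_simconfig"))
    config <- do.call(simulation_config, config)
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    sample_ids <- sprintf("S%04d", seq_len(n))
    idx_expr <- 10 + stats::rnorm(n, 0, 1) + stats::rnorm(n, 0, cfg$noise_sd)
    thr <- as.numeric(stats::quantile(idx_expr, cfg$true_cutpoint_quantile,
                                      type = 7))
    hi <- idx_expr > thr

    rate <- cfg$baseline_event_rate *
      ifelse(hi, cfg$hazard_ratio_hi_vs_lo, 1)
    t_event <- stats::rexp(n, rate)
    t_cens <- pmin(stats::rexp(n, cfg$censoring_rate), cfg$followup_horizon)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    L <- length(cfg$grade_levels)
    latent <- cfg$grade_shift * idx_expr + stats::rnorm(n, 0, 1)
    cuts <- stats::quantile(latent, probs = seq(0, 1, length.out = L + 1))
    cuts[1] <- -Inf; cuts[L + 1] <- Inf
    grade <- cut(latent, breaks = cuts, labels = cfg$grade_levels,
                 include.lowest = TRUE, ordered_result = TRUE)

    n_other <- cfg$n_genes - 1L
    other_ids <- sprintf("G%05d", seq_len(n_other))
    up_ids <- other_ids[seq_len(cfg$n_de_genes_up)]
    down_ids <- other_ids[cfg$n_de_genes_up + seq_len(cfg$n_de_genes_down)]
    base_mean <- stats::runif(n_other, 6, 12)
    expr <- matrix(stats::rnorm(n_other * n, 0, cfg$noise_sd),
                   nrow = n_other) + base_mean
    if (cfg$n_de_genes_up > 0)
      expr[match(up_ids, other_ids), hi] <-
        expr[match(up_ids, other_ids), hi] + cfg$de_log2_effect
    if (cfg$n_de_genes_down > 0)
      expr[match(down_ids, other_ids), hi] <-
        expr[match(down_ids, other_ids), hi] - cfg$de_log2_effect
    expression <- rbind(matrix(idx_expr, nrow = 1), expr)
    rownames(expression) <- c(cfg$index_gene_name, other_ids)
    colnames(expression) <- sample_ids

    clinical <- data.frame(sample_id = sample_ids, time = time,
                           event = event, grade = as.character(grade),
                           stringsAsFactors = FALSE)
    truth <- list(threshold = thr,
                  quantile = cfg$true_cutpoint_quantile,
                  hi = stats::setNames(hi, sample_ids),
                  up_genes = up_ids, down_genes = down_ids,
                  hazard_ratio = cfg$hazard_ratio_hi_vs_lo)
    structure(list(expression = expression, clinical = clinical,
                   truth = truth, config = cfg),
              class = "stratsurv_study")
  })
}

#' @export
print.stratsurv_study <- function(x, ...) {
  cat("Synthetic expression study:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples\n")
  cat("  index gene:", x$config$index_gene_name,
      " planted threshold:", round(x$truth$threshold, 3),
      " HR:", x$truth$hazard_ratio, "\n")
  cat("  events:", sum(x$clinical$event), "of", nrow(x$clinical), "\n")
  invisible(x)
}

#' Generate a synthetic gene-set collection
#'
#' Draws random gene sets in GMT layout. When `enriched_genes` is supplied
#' with a positive `enriched_set_overlap`, the first set is deliberately
#' over-sampled from those genes at the stated fraction, so downstream
#' enrichment recovery is testable.
#'
#' @param genes Character vector of available gene identifiers.
#' @param n_sets Number of sets (0 gives an empty collection).
#' @param set_size_range Integer pair, inclusive bounds on set size.
#' @param enriched_set_overlap Fraction of the first set drawn from
#'   `enriched_genes`.
#' @param enriched_genes Identifiers to over-sample in the first set.
#' @param seed Integer seed.
#' @return Named list of character vectors, with a `descriptions`
#'   attribute; write with [write_gmt()].
#' @export
generate_gene_sets <- function(genes, n_sets, set_size_range = c(10, 50),
                               enriched_set_overlap = 0,
                               enriched_genes = NULL, seed = 1) {
  if (length(set_size_range) != 2 || any(set_size_range < 1) ||
      set_size_range[1] > set_size_range[2])
    stop("set_size_range must be an increasing positive integer pair")
  if (set_size_range[2] > length(genes))
    stop("set sizes exceed the number of available genes")
  if (enriched_set_overlap < 0 || enriched_set_overlap > 1)
    stop("enriched_set_overlap must lie in [0, 1]")
  if (n_sets == 0)
    return(structure(list(), descriptions = character(0)))
  with_seed(seed, {
    sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                    replace = TRUE)
    sets <- vector("list", n_sets)
    for (i in seq_len(n_sets)) {
      if (i == 1 && enriched_set_overlap > 0 && length(enriched_genes) > 0) {
        k <- min(round(enriched_set_overlap * sizes[i]),
                 length(enriched_genes))
        planted <- sample(enriched_genes, k)
        rest <- sample(setdiff(genes, planted), sizes[i] - k)
        sets[[i]] <- sample(c(planted, rest))
      } else {
        sets[[i]] <- sample(genes, sizes[i])
      }
    }
    names(sets) <- sprintf("SET%04d", seq_len(n_sets))
    attr(sets, "descriptions") <-
      stats::setNames(sprintf("synthetic gene set %d", seq_len(n_sets)),
                      names(sets))
    sets
  })
}

#' Generate a synthetic IHC core table
#'
#' Emulates a tissue-microarray read-out: for each patient,
#' `cores_per_class` benign and malignant cores with percent positive cells
#' and integer staining intensity whose H-scores have the requested class
#' means in expectation. A latent target score is drawn Gaussian around the
#' class mean (sd 30), clamped to \[0, 300\], and decomposed into intensity
#' `ceiling(score / 100)` and percent `score / intensity`, so
#' `percent * intensity` reproduces the latent score.
#'
#' @param n_patients Number of patients.
#' @param cores_per_class Cores per tissue class per patient.
#' @param benign_mean_score,malignant_mean_score Target class means in
#'   \[0, 300\].
#' @param seed Integer seed.
#' @return Data frame with columns `patient_id`, `class`, `core`,
#'   `percent_positive`, `intensity`.
#' @export
generate_ihc_table <- function(n_patients, cores_per_class = 3,
                               benign_mean_score = 60,
                               malignant_mean_score = 160, seed = 1) {
  means <- c(benign = benign_mean_score, malignant = malignant_mean_score)
  if (any(means < 0) || any(means > 300))
    stop("class mean scores must lie in [0, 300]")
  if (n_patients < 1 || cores_per_class < 1)
    stop("n_patients and cores_per_class must be positive")
  with_seed(seed, {
    rows <- expand.grid(core = seq_len(cores_per_class),
                        class = c("benign", "malignant"),
                        patient_id = sprintf("P%03d", seq_len(n_patients)),
                        stringsAsFactors = FALSE)
    target <- stats::rnorm(nrow(rows), means[rows$class], 30)
    target <- pmin(pmax(target, 0), 300)
    intensity <- pmin(pmax(ceiling(target / 100), 0L), 3L)
    percent <- ifelse(intensity > 0, target / intensity, 0)
    data.frame(patient_id = rows$patient_id, class = rows$class,
               core = rows$core, percent_positive = percent,
               intensity = as.integer(intensity),
               stringsAsFactors = FALSE)
  })
}
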