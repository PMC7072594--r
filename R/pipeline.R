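# End-to-end orchestration: per-study cutpoint -> survival tests -> DE ->
# cross-study intersection -> enrichment, from a single config, with a run
# manifest.  Deterministic given config + seed.

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()].
#' Defaults mirror the published analysis: alpha 0.05, fold threshold 1.25,
#' shared genes required in >= 2 studies, 95% confidence intervals,
#' Mantel-Haenszel cutpoint search with a 0.1 minimum group fraction, EASE
#' enrichment statistic.
#'
#' @param studies List of study entries; each a list with `name`,
#'   `expression` (TSV path) and `clinical` (TSV path).
#' @param index_gene Name of the stratifying gene (must be present in
#'   every study).
#' @param min_group_fraction Minimum per-group fraction for the cutpoint.
#' @param alpha FDR significance level in \[0, 1\].
#' @param fold_threshold Fold-regulation threshold (> 1).
#' @param min_studies Studies required per direction for the intersection.
#' @param gene_sets Optional GMT path for enrichment.
#' @param out_dir Output directory.
#' @param seed Integer seed (used by the permutation correction).
#' @param ease Use the EASE enrichment statistic?
#' @param permutations Permutations for the selection-adjusted p (0 = off).
#' @param weighting Log-rank weighting for the cutpoint search.
#' @param collapse_duplicates Collapse duplicated probe ids on load?
#' @return A validated `stratsurv_config` list.
#' @export
pipeline_config <- function(studies, index_gene, min_group_fraction = 0.1,
                            alpha = 0.05, fold_threshold = 1.25,
                            min_studies = 2, gene_sets = NULL,
                            out_dir = "stratsurv_results", seed = 1,
                            ease = TRUE, permutations = 0,
                            weighting = "mantel-haenszel",
                            collapse_duplicates = FALSE) {
  if (length(studies) < 1) stop("config needs >= 1 study")
  for (s in studies)
    if (!all(c("name", "expression", "clinical") %in% names(s)))
      stop("each study entry needs name, expression and clinical fields")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (fold_threshold <= 1) stop("fold_threshold must exceed 1")
  if (min_studies < 1) stop("min_studies must be >= 1")
  structure(list(studies = studies, index_gene = index_gene,
                 min_group_fraction = min_group_fraction, alpha = alpha,
                 fold_threshold = fold_threshold, min_studies = min_studies,
                 gene_sets = gene_sets, out_dir = out_dir, seed = seed,
                 ease = ease, permutations = permutations,
                 weighting = weighting,
                 collapse_duplicates = collapse_duplicates),
            class = "stratsurv_config")
}

#' Read a flat key/value pipeline configuration file
#'
#' Plain-text format, one `key = value` per line, `#` comments allowed.
#' Studies are declared as `study.<name>.expression` and
#' `study.<name>.clinical` entries; remaining keys map to the arguments of
#' [pipeline_config()].
#'
#' @param path Configuration file path.
#' @return A `stratsurv_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(vapply(kv, length, integer(1)) != 2)
  if (length(bad) > 0)
    stop("malformed config line(s): ", paste(bad, collapse = ", "))
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, `[[`, character(1), 2)
  is_study <- grepl("^study\\.", keys)
  studies <- list()
  for (i in which(is_study)) {
    p <- strsplit(keys[i], ".", fixed = TRUE)[[1]]
    if (length(p) != 3 || !(p[3] %in% c("expression", "clinical")))
      stop("bad study key: ", keys[i])
    studies[[p[2]]] <- c(studies[[p[2]]],
                         stats::setNames(list(vals[i]), p[3]))
  }
  studies <- lapply(names(studies), function(nm)
    c(list(name = nm), studies[[nm]]))
  args <- list(studies = studies)
  num_keys <- c("min_group_fraction", "alpha", "fold_threshold",
                "min_studies", "seed", "permutations")
  for (i in which(!is_study)) {
    k <- keys[i]; v <- vals[i]
    args[[k]] <- if (k %in% num_keys) as.numeric(v)
                 else if (k == "ease") as.logical(v)
                 else v
  }
  do.call(pipeline_config, args)
}

load_study <- function(entry, cfg) {
  expr <- read_expression_matrix(entry$expression,
                                 collapse_duplicates = cfg$collapse_duplicates)
  clin <- read_clinical(entry$clinical)
  if (!(cfg$index_gene %in% rownames(expr)))
    stop(sprintf("index gene '%s' absent from study '%s'",
                 cfg$index_gene, entry$name))
  missing_expr <- setdiff(clin$sample_id, colnames(expr))
  if (length(missing_expr) > 0)
    stop(sprintf("study '%s': clinical samples missing from expression: %s",
                 entry$name, paste(missing_expr, collapse = ", ")))
  # samples without follow-up are excluded everywhere, and logged
  excluded <- setdiff(colnames(expr), clin$sample_id)
  expr <- expr[, clin$sample_id, drop = FALSE]
  list(name = entry$name, expression = expr, clinical = clin,
       n_in = length(clin$sample_id) + length(excluded),
       n_used = length(clin$sample_id), excluded = excluded)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full stratification pipeline
#'
#' For each study: locate the survival-optimal index-gene cutpoint, label
#' samples hi/lo, estimate Kaplan-Meier curves per group, run
#' Mantel-Haenszel and Gehan-Wilcoxon tests and a univariate Cox model on
#' continuous index expression, and compute the stratified
#' differential-expression table. Across studies: intersect significantly
#' regulated genes per direction and, when a gene-set collection is
#' configured, test the shared up- and down-sets for enrichment. All
#' results are written as TSV plus a JSON manifest; re-running with the
#' same config and seed reproduces the outputs byte for byte.
#'
#' @param config A `stratsurv_config` (or path to a flat config file).
#' @return Invisibly, the result bundle: per-study results, intersection,
#'   enrichment tables and manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  stopifnot(inherits(cfg, "stratsurv_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  studies <- lapply(cfg$studies, load_study, cfg = cfg)
  names(studies) <- vapply(studies, `[[`, character(1), "name")

  per_study <- lapply(studies, function(st) {
    idx <- st$expression[cfg$index_gene, ]
    cp <- find_optimal_cutpoint(idx, st$clinical,
                                min_group_fraction = cfg$min_group_fraction,
                                weighting = cfg$weighting)
    if (cfg$permutations > 0)
      cp <- selection_adjusted_p(cp, n_permutations = cfg$permutations,
                                 seed = cfg$seed)
    hi <- cp$labels == "hi"
    lr_mh <- logrank_test(st$clinical[hi, ], st$clinical[!hi, ],
                          "mantel-haenszel")
    lr_gw <- logrank_test(st$clinical[hi, ], st$clinical[!hi, ],
                          "gehan-wilcoxon")
    cox <- cox_univariate(idx, st$clinical)
    km_hi <- km_estimate(st$clinical[hi, ])
    km_lo <- km_estimate(st$clinical[!hi, ])
    de <- de_per_study(st$expression, cp$labels, alpha = cfg$alpha,
                       fold_threshold = cfg$fold_threshold,
                       drop_index = cfg$index_gene)
    list(study = st, cutpoint = cp, logrank = lr_mh, wilcoxon = lr_gw,
         cox = cox, km = list(hi = km_hi, lo = km_lo), de = de)
  })

  inter <- cross_study_intersection(lapply(per_study, `[[`, "de"),
                                    min_studies = cfg$min_studies)
  universe <- sort(unique(unlist(lapply(studies, function(st)
    setdiff(rownames(st$expression), cfg$index_gene)))))
  enrichment <- NULL
  if (!is.null(cfg$gene_sets)) {
    sets <- if (is.character(cfg$gene_sets)) read_gmt(cfg$gene_sets)
            else cfg$gene_sets
    enrichment <- list(
      up = enrich_gene_list(inter$up, sets, universe, alpha = cfg$alpha,
                            ease = cfg$ease),
      down = enrich_gene_list(inter$down, sets, universe,
                              alpha = cfg$alpha, ease = cfg$ease))
  }

  # ---- write the bundle ----------------------------------------------
  for (nm in names(per_study)) {
    ps <- per_study[[nm]]
    write_tsv(ps$cutpoint$candidates,
              file.path(cfg$out_dir, paste0("cutpoint_", nm, ".tsv")))
    summ <- list(study = nm, threshold = ps$cutpoint$optimal_threshold,
                 n_lo = ps$cutpoint$n_lo, n_hi = ps$cutpoint$n_hi,
                 mantel_haenszel = list(statistic = ps$logrank$statistic,
                                        p = ps$logrank$p_value),
                 gehan_wilcoxon = list(statistic = ps$wilcoxon$statistic,
                                       p = ps$wilcoxon$p_value),
                 cox = list(hr = ps$cox$hr, ci_low = ps$cox$ci_low,
                            ci_high = ps$cox$ci_high, p = ps$cox$p_value),
                 adjusted_p = ps$cutpoint$adjusted_p)
    jsonlite::write_json(summ,
                         file.path(cfg$out_dir, paste0("summary_", nm,
                                                       ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    km_df <- rbind(cbind(group = "hi", ps$km$hi$table),
                   cbind(group = "lo", ps$km$lo$table))
    write_tsv(km_df, file.path(cfg$out_dir, paste0("km_", nm, ".tsv")))
    write_tsv(ps$de, file.path(cfg$out_dir, paste0("de_", nm, ".tsv")))
    write_tsv(volcano_table(ps$de),
              file.path(cfg$out_dir, paste0("volcano_", nm, ".tsv")))
  }
  writeLines(inter$up, file.path(cfg$out_dir, "shared_up.txt"))
  writeLines(inter$down, file.path(cfg$out_dir, "shared_down.txt"))
  write_tsv(inter$conflict, file.path(cfg$out_dir, "conflicts.tsv"))
  if (!is.null(enrichment)) {
    write_tsv(enrichment$up, file.path(cfg$out_dir, "enrichment_up.tsv"))
    write_tsv(enrichment$down, file.path(cfg$out_dir, "enrichment_down.tsv"))
  }
  manifest <- list(
    package = "stratsurv",
    version = as.character(utils::packageVersion("stratsurv")),
    seed = cfg$seed,
    parameters = cfg[c("index_gene", "min_group_fraction", "alpha",
                       "fold_threshold", "min_studies", "ease",
                       "permutations", "weighting")],
    studies = lapply(studies, function(st)
      list(name = st$name, n_in = st$n_in, n_used = st$n_used,
           n_excluded = length(st$excluded), excluded = st$excluded)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(per_study = per_study, intersection = inter,
                 enrichment = enrichment, manifest = manifest,
                 config = cfg))
}
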