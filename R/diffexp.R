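# Stratified differential expression, the significance rule
# (p_FDR < alpha and |fold-regulation| > fold_threshold, both strict),
# cross-study intersection of regulated genes, and gene-set enrichment of
# the shared genes.

# Vectorized per-row two-sample t test (Welch or pooled) over a matrix.
row_t_test <- function(x_hi, x_lo, equal_variance = FALSE) {
  nh <- ncol(x_hi); nl <- ncol(x_lo)
  mh <- rowMeans(x_hi); ml <- rowMeans(x_lo)
  vh <- rowSums((x_hi - mh)^2) / (nh - 1)
  vl <- rowSums((x_lo - ml)^2) / (nl - 1)
  if (equal_variance) {
    df <- rep(nh + nl - 2, length(mh))
    sp2 <- ((nh - 1) * vh + (nl - 1) * vl) / df
    se2 <- sp2 * (1 / nh + 1 / nl)
  } else {
    a <- vh / nh; b <- vl / nl
    se2 <- a + b
    df <- se2^2 / (a^2 / (nh - 1) + b^2 / (nl - 1))
  }
  d <- mh - ml
  t <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, Inf * sign(d)))
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t), df),
              ifelse(d == 0, 1, 0))
  list(mean_hi = mh, mean_lo = ml, t = t, p = p, df = df)
}

#' Stratified differential expression for one study
#'
#' Per-gene two-tailed t test between high- and low-expresser samples,
#' Benjamini-Hochberg correction over all tested genes, and signed
#' fold-regulation from the log2 mean difference `d`: `2^d` if `d >= 0`,
#' else `-2^(-d)`. A gene is called significant when `p_FDR < alpha` and
#' `|fold_regulation| > fold_threshold`, both strict.
#'
#' @param expression Genes x samples log2 matrix with row and column names.
#' @param labels Character vector of "hi"/"lo" per sample; if named, names
#'   are matched to the expression columns. Each group needs >= 2 samples.
#' @param alpha FDR significance level (default 0.05).
#' @param fold_threshold Fold-regulation threshold (default 1.25).
#' @param equal_variance Pool variances in the t test? Default Welch.
#' @param drop_index Optional gene id (the stratifying gene) to exclude
#'   from testing.
#' @return Data frame of `DERecord` rows: gene, mean_lo, mean_hi, t, p,
#'   p_fdr, fold_regulation, direction ("up"/"down"/"none"), significant.
#' @export
de_per_study <- function(expression, labels, alpha = 0.05,
                         fold_threshold = 1.25, equal_variance = FALSE,
                         drop_index = NULL) {
  if (!is.matrix(expression) || is.null(rownames(expression)))
    stop("expression must be a matrix with gene row names")
  if (!is.null(names(labels))) {
    if (!all(colnames(expression) %in% names(labels)))
      stop("labels do not cover all expression samples")
    labels <- labels[colnames(expression)]
  }
  if (length(labels) != ncol(expression))
    stop("labels must match the expression columns")
  if (!all(labels %in% c("hi", "lo")))
    stop("labels must be 'hi' or 'lo'")
  if (!is.null(drop_index))
    expression <- expression[setdiff(rownames(expression), drop_index), ,
                             drop = FALSE]
  hi <- labels == "hi"
  if (sum(hi) < 2 || sum(!hi) < 2)
    stop("each group needs >= 2 samples")
  tt <- row_t_test(expression[, hi, drop = FALSE],
                   expression[, !hi, drop = FALSE], equal_variance)
  p_fdr <- bh_adjust(tt$p)
  d <- tt$mean_hi - tt$mean_lo
  fold <- ifelse(d >= 0, 2^d, -2^(-d))
  sig <- p_fdr < alpha & abs(fold) > fold_threshold
  direction <- ifelse(!sig, "none", ifelse(d > 0, "up", "down"))
  data.frame(gene = rownames(expression),
             mean_lo = tt$mean_lo, mean_hi = tt$mean_hi,
             t = tt$t, p = tt$p, p_fdr = p_fdr,
             fold_regulation = fold, direction = direction,
             significant = sig, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Cross-study intersection of regulated genes
#'
#' Counts, per direction independently, in how many studies each gene is
#' significantly regulated. Genes meeting `min_studies` in one direction
#' enter that shared set; genes meeting it in both directions are reported
#' only in the conflict table. Any gene significant up in some studies and
#' down in others is listed in the conflict table regardless (never
#' silently assigned).
#'
#' @param tables Named list of >= 2 `de_per_study()` tables sharing a gene
#'   namespace.
#' @param min_studies Minimum number of studies per direction (default 2).
#' @return A `stratsurv_intersection`: `up`, `down` (character vectors),
#'   `conflict` (data frame gene/n_up/n_down), and `membership` (gene,
#'   study, direction).
#' @export
cross_study_intersection <- function(tables, min_studies = 2) {
  if (!is.list(tables) || length(tables) < 2)
    stop("need >= 2 differential-expression tables")
  if (is.null(names(tables)))
    names(tables) <- sprintf("study%d", seq_along(tables))
  gene_lists <- lapply(tables, function(tb) tb$gene)
  shared_ns <- table(unlist(lapply(gene_lists, unique)))
  if (!any(shared_ns >= 2)) {
    warning("gene namespaces are disjoint across studies; empty result")
    return(structure(list(up = character(0), down = character(0),
                          conflict = data.frame(gene = character(0),
                                                n_up = integer(0),
                                                n_down = integer(0)),
                          membership = data.frame(gene = character(0),
                                                  study = character(0),
                                                  direction = character(0)),
                          min_studies = min_studies),
                     class = "stratsurv_intersection"))
  }
  memb <- do.call(rbind, lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    sig <- tb[tb$significant, , drop = FALSE]
    if (nrow(sig) == 0) return(NULL)
    data.frame(gene = sig$gene, study = nm, direction = sig$direction,
               stringsAsFactors = FALSE)
  }))
  if (is.null(memb))
    memb <- data.frame(gene = character(0), study = character(0),
                       direction = character(0))
  count_dir <- function(dir) {
    tab <- table(memb$gene[memb$direction == dir])
    stats::setNames(as.integer(tab), names(tab))
  }
  n_up <- count_dir("up"); n_down <- count_dir("down")
  genes <- as.character(union(names(n_up), names(n_down)))
  up_ct <- ifelse(genes %in% names(n_up), n_up[genes], 0L)
  down_ct <- ifelse(genes %in% names(n_down), n_down[genes], 0L)
  meets_up <- up_ct >= min_studies
  meets_down <- down_ct >= min_studies
  mixed <- up_ct > 0 & down_ct > 0
  conflict <- data.frame(gene = genes[mixed],
                         n_up = up_ct[mixed], n_down = down_ct[mixed],
                         row.names = NULL, stringsAsFactors = FALSE)
  both <- meets_up & meets_down
  structure(list(up = as.character(sort(genes[meets_up & !both])),
                 down = as.character(sort(genes[meets_down & !both])),
                 conflict = conflict,
                 membership = memb, min_studies = min_studies),
            class = "stratsurv_intersection")
}

#' @export
print.stratsurv_intersection <- function(x, ...) {
  cat("Cross-study intersection (>=", x$min_studies, "studies):",
      length(x$up), "shared up,", length(x$down), "shared down,",
      nrow(x$conflict), "direction conflicts\n")
  invisible(x)
}

#' Gene-set enrichment of a gene list
#'
#' Tests each set of a collection for over-representation of `gene_list`
#' within `universe` using [fisher_enrichment()] (EASE variant by default).
#' Results are ranked by p ascending with ties broken by fold enrichment
#' descending.
#'
#' @param gene_list Character vector of genes of interest.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()] or [generate_gene_sets()]).
#' @param universe Character vector containing at least all of `gene_list`.
#' @param alpha Significance threshold recorded per term (default 0.05).
#' @param ease Use the conservative EASE statistic (default TRUE)?
#' @return Data frame of `EnrichmentRecord` rows: term, description, k, K,
#'   n, N, p, fold_enrichment, significant, rank.
#' @export
enrich_gene_list <- function(gene_list, gene_sets, universe,
                             alpha = 0.05, ease = TRUE) {
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe))
    stop("universe must contain every gene of the list")
  empty <- data.frame(term = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0),
                      fold_enrichment = numeric(0),
                      significant = logical(0), rank = integer(0))
  if (length(gene_list) == 0 || length(gene_sets) == 0) return(empty)
  desc <- attr(gene_sets, "descriptions")
  N <- length(universe); n <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(members)
    k <- length(intersect(members, gene_list))
    if (K == 0)
      return(data.frame(term = nm,
                        description = if (!is.null(desc)) desc[[nm]] else "",
                        k = 0L, K = 0L, n = n, N = N, p = 1,
                        fold_enrichment = NA_real_, significant = FALSE,
                        stringsAsFactors = FALSE))
    fe <- fisher_enrichment(N, K, n, k, ease = ease)
    data.frame(term = nm,
               description = if (!is.null(desc)) desc[[nm]] else "",
               k = k, K = K, n = n, N = N, p = fe$p_value,
               fold_enrichment = fe$fold_enrichment,
               significant = fe$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  o <- order(out$p, -out$fold_enrichment, out$term)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Top enriched terms
#'
#' Convenience accessor for the `top_k` most significantly enriched terms
#' of an [enrich_gene_list()] table.
#'
#' @param enrichment Enrichment table.
#' @param top_k Number of terms to keep (default 10).
#' @return The first `top_k` rows by rank.
#' @export
top_terms <- function(enrichment, top_k = 10) {
  utils::head(enrichment[order(enrichment$rank), , drop = FALSE], top_k)
}

#' Volcano-plot export table
#'
#' Per gene: signed log2 fold-regulation, `-log10 p_FDR`, the significance
#' class, and a flag for the `top_n` most significant genes (for labeling).
#'
#' @param de_table A [de_per_study()] table.
#' @param top_n Number of most significant genes to flag (default 20).
#' @return Data frame: gene, log2_fold, neg_log10_p_fdr, class, top.
#' @export
volcano_table <- function(de_table, top_n = 20) {
  if (nrow(de_table) == 0) stop("empty differential-expression table")
  # |fold| >= 1 by construction, so this recovers the signed log2 difference
  log2_fold <- sign(de_table$fold_regulation) *
    log2(abs(de_table$fold_regulation))
  o <- order(de_table$p_fdr, -abs(de_table$fold_regulation))
  top <- logical(nrow(de_table))
  top[o[seq_len(min(top_n, nrow(de_table)))]] <- TRUE
  data.frame(gene = de_table$gene, log2_fold = log2_fold,
             neg_log10_p_fdr = -log10(de_table$p_fdr),
             class = de_table$direction, top = top,
             row.names = NULL, stringsAsFactors = FALSE)
}
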