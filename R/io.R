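# Plain-text readers and writers: expression TSV (first column gene id),
# clinical TSV (sample_id, time, event[, grade]), GMT gene sets, IHC core
# tables, and study export.

#' Read a gene-expression matrix from TSV
#'
#' First column holds gene identifiers, remaining columns one sample each.
#' Malformed numeric cells are reported with row/column coordinates.
#' Duplicate gene ids are rejected unless `collapse_duplicates = TRUE`, in
#' which case the probe with the highest mean is kept per gene.
#'
#' @param path TSV file path.
#' @param collapse_duplicates Collapse duplicated gene ids (max mean)?
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
read_expression_matrix <- function(path, collapse_duplicates = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("expression table needs gene ids plus >= 1 sample")
  genes <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !(toupper(trimws(vals)) %in% c("NA", "")),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("malformed numeric cell at row %d, column '%s'",
                 bad[1, 1] + 1L, colnames(vals)[bad[1, 2]]))
  if (any(is.na(num))) stop("expression matrix contains missing values")
  rownames(num) <- genes
  if (anyDuplicated(genes)) {
    if (!collapse_duplicates)
      stop("duplicated gene ids: ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
    means <- rowMeans(num)
    keep <- unlist(lapply(split(seq_along(genes), genes),
                          function(ix) ix[which.max(means[ix])]))
    num <- num[sort(keep), , drop = FALSE]
  }
  num
}

#' Write a gene-expression matrix as TSV
#'
#' @param expression Genes x samples matrix with dimnames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(expression, path) {
  df <- data.frame(gene = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical follow-up table from TSV
#'
#' Expects columns `sample_id`, `time`, `event` and optionally `grade`.
#' Validation: time > 0, event in \{0, 1\}, unique sample ids; offending
#' rows are named in the error.
#'
#' @param path TSV file path.
#' @return Data frame of survival records.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("sample_id", "time", "event")
  if (!all(req %in% names(df)))
    stop("clinical table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample ids in clinical table")
  bad_ev <- which(!(df$event %in% c(0, 1)))
  if (length(bad_ev) > 0)
    stop("event must be 0 or 1; offending rows: ",
         paste(utils::head(bad_ev, 5), collapse = ", "))
  bad_t <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad_t) > 0)
    stop("time must be finite and > 0; offending rows: ",
         paste(utils::head(bad_t, 5), collapse = ", "))
  df$event <- as.integer(df$event)
  df
}

#' Write a clinical table as TSV
#' @param clinical Data frame with sample_id, time, event and optional
#'   grade columns.
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then members. Lines
#' with fewer than three fields are rejected with their line numbers;
#' duplicated members within a set are deduplicated with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, integer(1)) < 3)
  if (length(short) > 0)
    stop("GMT lines with < 3 fields at line(s): ",
         paste(short, collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  dups <- vapply(sets, anyDuplicated, integer(1)) > 0
  if (any(dups)) {
    warning("duplicated members within set(s): ",
            paste(names(sets)[dups], collapse = ", "),
            "; deduplicated")
    sets <- lapply(sets, unique)
  }
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2), names(sets))
  sets
}

#' Write a gene-set collection as GMT
#' @param gene_sets Named list of character vectors; an optional
#'   `descriptions` attribute supplies the second field.
#' @param path Output path.
#' @export
write_gmt <- function(gene_sets, path) {
  desc <- attr(gene_sets, "descriptions")
  lines <- vapply(names(gene_sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an IHC core table from TSV
#'
#' Expects columns `patient_id`, `class`, `percent_positive`, `intensity`;
#' validates ranges and appends the H-score column.
#'
#' @param path TSV file path.
#' @return Data frame with an added `score` column.
#' @export
read_ihc_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("patient_id", "class", "percent_positive", "intensity")
  if (!all(req %in% names(df)))
    stop("IHC table must have columns: ", paste(req, collapse = ", "))
  df$score <- ihc_score(df$percent_positive, df$intensity)
  df
}

#' Compare IHC H-scores between tissue classes
#'
#' Averages core H-scores per patient and class, then compares the two
#' classes with a two-tailed t test (paired if every patient has both
#' classes and `paired = TRUE`).
#'
#' @param ihc IHC table (as from [read_ihc_table()] or
#'   [generate_ihc_table()]).
#' @param paired Use a paired test on per-patient differences?
#' @return A `stratsurv_test`.
#' @export
ihc_class_test <- function(ihc, paired = FALSE) {
  if (is.null(ihc$score))
    ihc$score <- ihc_score(ihc$percent_positive, ihc$intensity)
  agg <- stats::aggregate(score ~ patient_id + class, data = ihc, FUN = mean)
  classes <- sort(unique(agg$class))
  if (length(classes) != 2) stop("IHC table must contain exactly 2 classes")
  a <- agg[agg$class == classes[1], ]
  b <- agg[agg$class == classes[2], ]
  if (paired) {
    common <- intersect(a$patient_id, b$patient_id)
    if (length(common) < 2) stop("paired test needs >= 2 complete pairs")
    diffs <- a$score[match(common, a$patient_id)] -
      b$score[match(common, b$patient_id)]
    # one-sample t on the per-patient differences
    n <- length(diffs); m <- mean(diffs); s <- stats::sd(diffs)
    if (s == 0)
      return(new_test_result(if (m == 0) 0 else Inf * sign(m),
                             if (m == 0) 1 else 0,
                             method = "paired two-tailed t test",
                             degenerate = TRUE))
    tstat <- m / (s / sqrt(n))
    return(new_test_result(tstat, 2 * stats::pt(-abs(tstat), n - 1),
                           df = n - 1, method = "paired two-tailed t test"))
  }
  t_test_two_tailed(a$score, b$score)
}

#' Export a synthetic study to disk
#'
#' Writes the expression matrix and clinical table as TSV and the planted
#' truth as JSON into a directory.
#'
#' @param study A `stratsurv_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "stratsurv_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_expr <- file.path(dir, "expression.tsv")
  p_clin <- file.path(dir, "clinical.tsv")
  p_truth <- file.path(dir, "truth.json")
  write_expression_matrix(study$expression, p_expr)
  write_clinical(study$clinical, p_clin)
  truth <- study$truth
  truth$hi <- as.list(truth$hi)
  jsonlite::write_json(truth, p_truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(expression = p_expr, clinical = p_clin, truth = p_truth))
}
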