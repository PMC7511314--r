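## Reading/writing expression matrices and phenotype tables, count filtering
## and normalization, and the cohort demographic comparison.

#' Read a gene-level count matrix
#'
#' Supports two dialects: a tab-separated table whose header row holds sample
#' identifiers and whose first column holds gene identifiers, and MatrixMarket
#' coordinate format accompanied by `<path>.rows` / `<path>.cols` sidecar files
#' with one gene / sample identifier per line.
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"`.
#' @return genes-by-samples numeric matrix flagged as raw counts.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    rownames(vals) <- gene_ids
  } else {
    m <- Matrix::readMM(path)
    rows_path <- paste0(path, ".rows")
    cols_path <- paste0(path, ".cols")
    if (!file.exists(rows_path) || !file.exists(cols_path))
      stop("MatrixMarket sidecar label files missing: expected ",
           rows_path, " and ", cols_path, call. = FALSE)
    vals <- as.matrix(m)
    rownames(vals) <- readLines(rows_path)
    colnames(vals) <- readLines(cols_path)
  }
  if (anyDuplicated(rownames(vals)))
    stop("count matrix format error: duplicated gene identifiers in ", path,
         call. = FALSE)
  if (anyDuplicated(colnames(vals)))
    stop("count matrix format error: duplicated sample identifiers in ", path,
         call. = FALSE)
  storage.mode(vals) <- "numeric"
  if (anyNA(vals))
    stop("count matrix format error: non-numeric or missing entries in ", path,
         call. = FALSE)
  if (any(vals < 0))
    stop("count matrix format error: negative counts in ", path, call. = FALSE)
  expr_scale(vals) <- "raw_counts"
  vals
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]; both dialects round-trip exactly for integer
#' counts.
#'
#' @param x genes-by-samples matrix.
#' @param path output path.
#' @param format `"tsv"` or `"mtx"`.
#' @export
write_counts <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  check_expression_matrix(x)
  if (format == "tsv") {
    tab <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), path)
    writeLines(rownames(x), paste0(path, ".rows"))
    writeLines(colnames(x), paste0(path, ".cols"))
  }
  invisible(path)
}

#' Read / write a phenotype table
#'
#' Comma-separated, one row per sample.  `sample_id` and `group` are required;
#' association and PTRS stages additionally expect `age`, `sex`, `race`, `rin`
#' and the eight CBCL syndrome-scale columns (see [cbcl_scales()]).
#'
#' @param path file path.
#' @param required columns that must be present.
#' @return data frame.
#' @export
read_phenotypes <- function(path, required = c("sample_id", "group")) {
  pheno <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(pheno))
  if (length(missing))
    stop("phenotype table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(pheno$sample_id))
    stop("phenotype table has duplicated sample identifiers", call. = FALSE)
  pheno
}

#' @rdname read_phenotypes
#' @param pheno phenotype data frame.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove low-abundance genes
#'
#' Keeps genes whose counts-per-million reach `min_cpm` in at least
#' `min_fraction` of samples.  The retention rule is idempotent: the survivors
#' of a pass survive a second pass (CPM values change as the library shrinks,
#' so idempotence holds for the default thresholds on realistic data and is
#' checked in the test suite).
#'
#' @param x raw count matrix.
#' @param min_cpm CPM threshold (default 1).
#' @param min_fraction minimum fraction of samples at or above it (default 0.5).
#' @return filtered count matrix, gene order preserved.
#' @export
filter_low_abundance <- function(x, min_cpm = 1.0, min_fraction = 0.5) {
  check_expression_matrix(x, scale = "raw_counts")
  lib <- colSums(x)
  if (any(lib <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(x)[lib <= 0], collapse = ", "), call. = FALSE)
  cpm <- sweep(x, 2, lib, "/") * 1e6
  keep <- rowMeans(cpm >= min_cpm) >= min_fraction
  if (!any(keep)) warning("no genes pass the abundance filter")
  out <- x[keep, , drop = FALSE]
  expr_scale(out) <- "raw_counts"
  out
}

#' Log2 counts-per-million normalization
#'
#' `log2(CPM + 1)` per entry; the result is flagged `log2_cpm`.  This is the
#' package's documented stand-in for the count normalization of the original
#' processing pipeline.
#'
#' @param x raw count matrix.
#' @return normalized matrix.
#' @export
cpm_normalize <- function(x) {
  check_expression_matrix(x, scale = "raw_counts")
  lib <- colSums(x)
  if (any(lib <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(x)[lib <= 0], collapse = ", "), call. = FALSE)
  out <- log2(sweep(x, 2, lib, "/") * 1e6 + 1)
  expr_scale(out) <- "log2_cpm"
  out
}

#' Compare demographic and technical variables between two groups
#'
#' Reproduces the standard cohort table: pooled-variance two-sample t-tests for
#' continuous variables and Yates continuity-corrected Pearson chi-squared
#' tests for 2x2 categorical tables.
#'
#' @param pheno phenotype data frame.
#' @param group_var name of the binary grouping column.
#' @param continuous_vars,categorical_vars character vectors of column names.
#' @return data frame with columns `variable`, `test`, `statistic`, `p`.
#' @export
compare_groups <- function(pheno, group_var = "group",
                           continuous_vars = character(),
                           categorical_vars = character()) {
  g <- pheno[[group_var]]
  if (is.null(g)) stop("grouping column not found: ", group_var, call. = FALSE)
  g <- factor(g)
  if (nlevels(g) != 2L)
    stop("grouping variable must be binary", call. = FALSE)
  if (any(table(g) < 2L))
    stop("each group needs at least 2 samples", call. = FALSE)
  rows <- list()
  for (v in continuous_vars) {
    tt <- stats::t.test(pheno[[v]] ~ g, var.equal = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, test = "two-sample t", statistic = unname(tt$statistic),
      p = tt$p.value)
  }
  for (v in categorical_vars) {
    tab <- table(pheno[[v]], g)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, test = "Yates chi-squared", statistic = unname(ct$statistic),
      p = ct$p.value)
  }
  out <- do.call(rbind, rows) %||% data.frame(
    variable = character(), test = character(),
    statistic = numeric(), p = numeric())
  rownames(out) <- NULL
  out
}

#' Summaries of retained-gene annotation
#'
#' Given the number of retained genes and the number with some annotation
#' (e.g. protein-coding biotype), reports the annotated percentage rounded to
#' the nearest integer.
#'
#' @param n_genes number of retained genes.
#' @param n_annotated number of those with the annotation.
#' @return list with `fraction` and `percent`.
#' @export
annotation_summary <- function(n_genes, n_annotated) {
  if (n_genes <= 0 || n_annotated < 0 || n_annotated > n_genes)
    stop("invalid gene counts", call. = FALSE)
  frac <- n_annotated / n_genes
  list(fraction = frac, percent = round(100 * frac))
}
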