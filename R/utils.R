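#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

#' Expression-matrix scale flag
#'
#' Expression matrices are plain numeric matrices (genes in rows, samples in
#' columns) carrying a `"expr_scale"` attribute, either `"raw_counts"` or
#' `"log2_cpm"`.
#'
#' @param x a genes-by-samples numeric matrix.
#' @return the scale string, defaulting to `"raw_counts"` when unset.
#' @export
expr_scale <- function(x) attr(x, "expr_scale") %||% "raw_counts"

`expr_scale<-` <- function(x, value) {
  attr(x, "expr_scale") <- match.arg(value, c("raw_counts", "log2_cpm"))
  x
}

check_expression_matrix <- function(x, scale = NULL, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric genes-by-samples matrix", arg), call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("'%s' must have gene row names and sample column names", arg), call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(sprintf("'%s' has duplicated gene identifiers", arg), call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(sprintf("'%s' has duplicated sample identifiers", arg), call. = FALSE)
  if (!is.null(scale) && !identical(expr_scale(x), scale))
    stop(sprintf("'%s' must be on the %s scale (found %s)", arg, scale, expr_scale(x)),
         call. = FALSE)
  invisible(x)
}

#' Residualize genes on sample-level covariates
#'
#' Removes, gene by gene, the least-squares fit on a sample-level design
#' (an intercept is always included).  Used before SVD-based surrogate
#' variable estimation and before network construction.
#'
#' @param x genes-by-samples numeric matrix.
#' @param covariates samples-by-p numeric matrix (or NULL for intercept only).
#' @return matrix of residuals with the dimensions and dimnames of `x`.
#' @export
residualize <- function(x, covariates = NULL) {
  n <- ncol(x)
  C <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (qr(C)$rank < ncol(C))
    stop("covariate matrix is rank deficient", call. = FALSE)
  qc <- qr(C)
  ## residual of each row of x on C: x - (x Q) Q'
  Q <- qr.Q(qc)
  x - (x %*% Q) %*% t(Q)
}

#' Numeric covariate matrix from a phenotype table
#'
#' Deterministic model matrix used by the SVA, association and PTRS stages:
#' numeric columns pass through; factor/character/logical columns (sex, race
#' style binaries) are coerced to 0/1 indicators.
#'
#' @param pheno phenotype data frame.
#' @param covariate_names columns to include, in order.
#' @return samples-by-p numeric matrix (NULL when no names given).
#' @export
covariate_matrix <- function(pheno, covariate_names) {
  if (length(covariate_names) == 0L) return(NULL)
  missing <- setdiff(covariate_names, names(pheno))
  if (length(missing))
    stop("phenotype table lacks covariate column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  cols <- lapply(covariate_names, function(v) {
    col <- pheno[[v]]
    if (is.factor(col) || is.character(col)) col <- as.integer(factor(col)) - 1L
    if (is.logical(col)) col <- as.integer(col)
    as.numeric(col)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariate_names
  rownames(m) <- pheno$sample_id
  m
}

check_alignment <- function(sample_ids, other_ids, what) {
  if (length(sample_ids) != length(other_ids) || !all(sample_ids == other_ids))
    stop(sprintf("sample identifiers of %s are not aligned with the phenotype table", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Remove the per-sample common mode
#'
#' Subtracts each sample's mean across genes.  On small gene panels, dividing
#' by the library size during CPM normalization leaks a common-mode mixture
#' of the dominant expression factors into every gene; removing it before
#' network construction keeps module connectivity local.
#'
#' @param x genes-by-samples numeric matrix (log scale).
#' @return matrix with zero column means.
#' @export
center_samples <- function(x) {
  sweep(x, 2L, colMeans(x))
}

## Stage seeds derived from one base seed by a fixed counter scheme; keeps the
## derived seed a valid 32-bit integer for small base seeds.
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 97 + stage_index) %% .Machine$integer.max)
}

#' CBCL syndrome scale names
#'
#' The eight empirically derived syndrome scales of the Child Behavior
#' Checklist, as column names used throughout the package.
#'
#' @return character vector of length 8.
#' @export
cbcl_scales <- function() {
  c("anxious_depressed", "withdrawn_depressed", "somatic_complaints",
    "social_problems", "thought_problems", "attention_problems",
    "rule_breaking", "aggressive_behavior")
}
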