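## Signature-based leukocyte deconvolution by iterative least squares:
## per-sample OLS on the signature columns with successive elimination of
## negative coefficients, then clamping and normalization to proportions.

#' Estimate cell-type proportions from bulk expression
#'
#' For every sample, regresses its (linear-scale) expression over the shared
#' genes on the signature columns by ordinary least squares; while any
#' coefficient is negative, the most negative cell type is dropped (ties
#' broken toward the lower column index) and the fit repeated; remaining
#' negatives are clamped to zero and the coefficients normalized to sum to 1.
#'
#' @param x genes-by-samples bulk matrix on the linear (unlogged) scale —
#'   mixing is linear in abundance, so log-scale input is refused.
#' @param signature genes-by-celltypes signature matrix.
#' @return samples-by-celltypes proportion matrix (rows sum to 1).
#' @export
estimate_proportions <- function(x, signature) {
  if (identical(expr_scale(x), "log2_cpm"))
    stop("deconvolution requires linear-scale expression, not log2_cpm",
         call. = FALSE)
  shared <- intersect(rownames(x), rownames(signature))
  if (length(shared) < 2)
    stop("fewer than 2 genes shared between expression and signature",
         call. = FALSE)
  S <- signature[shared, , drop = FALSE]
  qs <- qr(S)
  if (qs$rank < ncol(S)) {
    dep <- colnames(S)[qs$pivot[seq(qs$rank + 1L, ncol(S))]]
    stop("signature matrix is rank deficient on shared genes; collinear column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  Y <- x[shared, , drop = FALSE]
  k <- ncol(S)
  out <- matrix(0, nrow = ncol(Y), ncol = k,
                dimnames = list(colnames(Y), colnames(S)))
  for (j in seq_len(ncol(Y))) {
    active <- seq_len(k)
    coefs <- numeric(k)
    repeat {
      fit <- qr.coef(qr(S[, active, drop = FALSE]), Y[, j])
      if (all(fit >= 0) || length(active) == 1L) {
        coefs[active] <- pmax(fit, 0)
        break
      }
      drop_idx <- which.min(fit)  # first minimum = lower column index on ties
      active <- active[-drop_idx]
    }
    tot <- sum(coefs)
    if (tot <= 0) {
      warning("sample ", colnames(Y)[j],
              " has no positive signature fit; proportions set to NA")
      coefs <- rep(NA_real_, k)
    } else {
      coefs <- coefs / tot
    }
    out[j, ] <- coefs
  }
  out
}

#' Test per-cell-type proportion differences between two groups
#'
#' Two-sample t-test of each cell type's estimated proportion across a binary
#' phenotype variable.  Degenerate (constant) proportions are flagged with an
#' NA statistic rather than an error.
#'
#' @param props samples-by-celltypes proportion matrix.
#' @param pheno phenotype data frame aligned with `props` rows.
#' @param var name of the binary grouping column.
#' @return data frame with columns `cell_type`, `statistic`, `p`, `degenerate`.
#' @export
test_proportion_differences <- function(props, pheno, var = "group") {
  check_alignment(pheno$sample_id, rownames(props), "proportion matrix")
  g <- factor(pheno[[var]])
  if (nlevels(g) != 2L) stop("grouping variable must be binary", call. = FALSE)
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples", call. = FALSE)
  rows <- lapply(colnames(props), function(ct) {
    v <- props[, ct]
    degenerate <- stats::var(v, na.rm = TRUE) == 0 || all(is.na(v))
    if (degenerate) {
      data.frame(cell_type = ct, statistic = NA_real_, p = NA_real_,
                 degenerate = TRUE)
    } else {
      tt <- stats::t.test(v ~ g, var.equal = TRUE)
      data.frame(cell_type = ct, statistic = unname(tt$statistic),
                 p = tt$p.value, degenerate = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
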