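## Polytranscript risk scoring: per-gene NB effect weights, p-value
## thresholded linear composite scores, stratified k-fold cross-validation,
## and scoring with externally supplied disorder weight tables.

default_thresholds <- function() c(0.001, 0.01, 0.05, 0.1, 0.5, 1.0)

#' Train per-gene transcript weights for one CBCL scale
#'
#' Per gene, the NB2 regression of the scale's t-score on the standardized
#' gene expression plus covariates within the training samples; the gene's
#' coefficient and Wald p-value become its weight.  Genes constant within the
#' subset get weight 0, p = 1, and a `constant` flag.
#'
#' @param x normalized (log2-CPM) genes-by-samples matrix.
#' @param pheno phenotype data frame aligned with columns of `x`.
#' @param scale CBCL scale name.
#' @param covariate_names covariates included in each per-gene model.
#' @param svs optional surrogate variables.
#' @param samples training subset (sample identifiers); default all.
#' @return `transcript_weights` data frame: `gene`, `beta`, `p`, `constant`,
#'   with the scale recorded in the `source` attribute.
#' @export
train_weights <- function(x, pheno, scale,
                          covariate_names = c("age", "sex", "race", "rin"),
                          svs = NULL, samples = NULL) {
  check_alignment(pheno$sample_id, colnames(x), "expression matrix")
  if (is.null(samples)) samples <- pheno$sample_id
  idx <- match(samples, pheno$sample_id)
  if (anyNA(idx)) stop("unknown sample identifiers in 'samples'", call. = FALSE)
  if (length(idx) < 20L)
    stop("training subset must contain at least 20 samples", call. = FALSE)
  ph <- pheno[idx, , drop = FALSE]
  svsub <- NULL
  if (!is.null(svs)) {
    svmat <- if (inherits(svs, "surrogate_variables")) svs$sv else as.matrix(svs)
    svsub <- svmat[idx, , drop = FALSE]
  }
  Xbase <- build_design(ph, covariate_names, svsub)
  y <- ph[[scale]]
  if (is.null(y)) stop("phenotype table lacks scale column: ", scale, call. = FALSE)
  sub <- x[, idx, drop = FALSE]
  X <- cbind(Xbase[, 1L, drop = FALSE], gene = 0, Xbase[, -1L, drop = FALSE])
  res <- matrix(NA_real_, nrow = nrow(sub), ncol = 2L)
  const <- logical(nrow(sub))
  for (g in seq_len(nrow(sub))) {
    expr <- sub[g, ]
    s <- stats::sd(expr)
    if (s == 0) {
      res[g, ] <- c(0, 1); const[g] <- TRUE
      next
    }
    X[, "gene"] <- (expr - mean(expr)) / s
    fit <- fit_nb_glm(y, X)
    res[g, ] <- c(fit$coefficients[["gene"]], fit$p[["gene"]])
  }
  out <- data.frame(gene = rownames(sub), beta = res[, 1L], p = res[, 2L],
                    constant = const, stringsAsFactors = FALSE)
  attr(out, "source") <- scale
  class(out) <- c("transcript_weights", "data.frame")
  out
}

#' Score samples with a transcript weight table
#'
#' `score_i = sum over genes with p <= threshold of beta_g * z_ig`, where the
#' standardization of each gene uses the supplied (training-derived) means
#' and SDs.  An empty gene selection yields all-zero scores with an
#' `empty = TRUE` attribute.
#'
#' @param x normalized genes-by-samples matrix of the samples to score.
#' @param weights a [train_weights()] table (columns `gene`, `beta`, `p`).
#' @param p_threshold inclusion threshold (inclusive; 1.0 keeps all genes).
#' @param center,scale named vectors of training means and SDs per gene;
#'   when omitted they are computed from `x` itself (appropriate only for
#'   external-weights scoring of a whole cohort).
#' @return named numeric score vector (attribute `n_genes` = genes used).
#' @export
score_samples <- function(x, weights, p_threshold = 1.0,
                          center = NULL, scale = NULL) {
  missing <- setdiff(weights$gene, rownames(x))
  if (length(missing))
    stop("expression matrix lacks weighted gene(s): ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  if (is.null(center)) center <- rowMeans(x[weights$gene, , drop = FALSE])
  if (is.null(scale))
    scale <- apply(x[weights$gene, , drop = FALSE], 1L, stats::sd)
  sel <- weights$p <= p_threshold
  genes <- weights$gene[sel]
  usable <- genes[scale[genes] > 0]
  if (!length(usable)) {
    out <- stats::setNames(rep(0, ncol(x)), colnames(x))
    attr(out, "empty") <- TRUE
    attr(out, "n_genes") <- 0L
    return(out)
  }
  z <- (x[usable, , drop = FALSE] - center[usable]) / scale[usable]
  beta <- weights$beta[match(usable, weights$gene)]
  out <- drop(crossprod(z, beta))
  names(out) <- colnames(x)
  attr(out, "n_genes") <- length(usable)
  out
}

make_stratified_folds <- function(group, k, seed) {
  set.seed(seed)
  fold <- integer(length(group))
  for (lev in unique(group)) {
    idx <- sample(which(group == lev))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  if (any(tabulate(fold, k) < 2L))
    stop("degenerate folds: every fold needs at least 2 samples", call. = FALSE)
  fold
}

evaluate_score <- function(y, score, Xbase) {
  if (stats::sd(score) == 0)
    return(c(r2 = 0, p = 1))
  X <- cbind(Xbase[, 1L, drop = FALSE], score = score, Xbase[, -1L, drop = FALSE])
  fit <- fit_nb_glm(y, X)
  null_fit <- fit_nb_glm(y, Xbase)
  c(r2 = nagelkerke_r2(fit, null_fit), p = unname(fit$p["score"]))
}

#' Cross-validated polytranscript risk scores for CBCL scales
#'
#' Stratified (by group) k-fold cross-validation: weights are trained on the
#' training folds, the withheld fold is scored using training-fold
#' standardization only, and the pooled withheld scores are evaluated per
#' p-value threshold by the NB2 fit of the t-score on score plus covariates
#' against the covariate-only null (Nagelkerke R-squared and Wald p).
#' BH-FDR is applied across the six thresholds within each scale.
#'
#' @param x normalized genes-by-samples matrix.
#' @param pheno phenotype data frame (needs `group` for stratification).
#' @param scales scales to evaluate (default all eight).
#' @param covariate_names,svs covariate adjustment as elsewhere.
#' @param k number of folds (default 5).
#' @param thresholds p-value threshold grid; fixed length 6.
#' @param seed seed controlling the fold assignment.
#' @param pooled if TRUE (default) one R-squared per threshold from the
#'   concatenated withheld folds; if FALSE the per-fold average R-squared
#'   with Fisher-combined p-values.
#' @param store_weights if TRUE, keep the per-(scale, fold) weight tables in
#'   the result (for audits of training/withheld separation).
#' @return object of class `ptrs_result`: list with `table` (scale,
#'   threshold, n_genes, r2, p, fdrp), `summary` (scale, max_r2, min_p,
#'   fdrp), `folds`, `thresholds`, `seed`.
#' @export
crossvalidate_ptrs <- function(x, pheno, scales = cbcl_scales(),
                               covariate_names = c("age", "sex", "race", "rin"),
                               svs = NULL, k = 5L,
                               thresholds = default_thresholds(), seed = 1L,
                               pooled = TRUE, store_weights = FALSE) {
  if (length(thresholds) != 6L)
    stop("the threshold grid has fixed length 6", call. = FALSE)
  check_alignment(pheno$sample_id, colnames(x), "expression matrix")
  fold <- make_stratified_folds(pheno$group, k, seed)
  Xbase_all <- build_design(pheno, covariate_names,
                            if (is.null(svs)) NULL else
                              (if (inherits(svs, "surrogate_variables")) svs$sv else svs))
  table_rows <- list()
  kept_weights <- list()
  for (sc in scales) {
    scores <- matrix(NA_real_, nrow = ncol(x), ncol = length(thresholds))
    n_genes_used <- matrix(0L, nrow = k, ncol = length(thresholds))
    for (f in seq_len(k)) {
      train_ids <- pheno$sample_id[fold != f]
      test_idx <- which(fold == f)
      w <- train_weights(x, pheno, sc, covariate_names, svs, samples = train_ids)
      if (store_weights) kept_weights[[paste(sc, f, sep = ".")]] <- w
      tr <- x[, fold != f, drop = FALSE]
      ctr <- rowMeans(tr)
      sds <- apply(tr, 1L, stats::sd)
      for (t in seq_along(thresholds)) {
        s <- score_samples(x[, test_idx, drop = FALSE], w, thresholds[t],
                           center = ctr, scale = sds)
        scores[test_idx, t] <- s
        n_genes_used[f, t] <- attr(s, "n_genes")
      }
    }
    y <- pheno[[sc]]
    for (t in seq_along(thresholds)) {
      if (pooled) {
        ev <- evaluate_score(y, scores[, t], Xbase_all)
      } else {
        per_fold <- vapply(seq_len(k), function(f) {
          idx <- fold == f
          evaluate_score(y[idx], scores[idx, t], Xbase_all[idx, , drop = FALSE])
        }, numeric(2))
        chi <- -2 * sum(log(pmax(per_fold["p", ], 1e-300)))
        ev <- c(r2 = mean(per_fold["r2", ]),
                p = stats::pchisq(chi, df = 2 * k, lower.tail = FALSE))
      }
      table_rows[[length(table_rows) + 1L]] <- data.frame(
        scale = sc, threshold = thresholds[t],
        n_genes = round(mean(n_genes_used[, t])),
        r2 = unname(ev["r2"]), p = unname(ev["p"]))
    }
  }
  tab <- do.call(rbind, table_rows)
  tab$fdrp <- NA_real_
  for (sc in scales)
    tab$fdrp[tab$scale == sc] <- bh_fdr(tab$p[tab$scale == sc])
  summ <- do.call(rbind, lapply(scales, function(sc) {
    sub <- tab[tab$scale == sc, ]
    i <- which.min(sub$p)
    data.frame(scale = sc, max_r2 = max(sub$r2), min_p = sub$p[i],
               fdrp = sub$fdrp[i])
  }))
  structure(list(table = tab, summary = summ,
                 folds = stats::setNames(fold, pheno$sample_id),
                 thresholds = thresholds, seed = seed, mode = "cv",
                 weights = if (store_weights) kept_weights),
            class = "ptrs_result")
}

#' Score a cohort with externally derived disorder weight tables
#'
#' For each external weight table (one per disorder), each of the eight CBCL
#' scales and each of the six thresholds — 48 tests per disorder — scores all
#' samples (cohort standardization; genes intersected with the cohort, with
#' the intersection size reported) and evaluates the NB2 fit against the
#' covariate-only null.  BH-FDR is applied within each disorder.
#'
#' @param x normalized genes-by-samples matrix.
#' @param pheno phenotype data frame.
#' @param external_weights named list of weight tables (columns `gene`,
#'   `beta`, `p`); names label the source disorders.
#' @param covariate_names,svs,thresholds,scales as in [crossvalidate_ptrs()].
#' @return object of class `ptrs_result` with a `disorder` column in `table`
#'   and `summary`, and `n_shared_genes` per disorder.
#' @export
external_ptrs <- function(x, pheno, external_weights,
                          covariate_names = c("age", "sex", "race", "rin"),
                          svs = NULL, thresholds = default_thresholds(),
                          scales = cbcl_scales()) {
  if (length(thresholds) != 6L)
    stop("the threshold grid has fixed length 6", call. = FALSE)
  if (is.null(names(external_weights)) || any(!nzchar(names(external_weights))))
    stop("external weight tables must be named by source disorder", call. = FALSE)
  check_alignment(pheno$sample_id, colnames(x), "expression matrix")
  Xbase <- build_design(pheno, covariate_names,
                        if (is.null(svs)) NULL else
                          (if (inherits(svs, "surrogate_variables")) svs$sv else svs))
  rows <- list()
  n_shared <- stats::setNames(integer(length(external_weights)),
                              names(external_weights))
  for (dis in names(external_weights)) {
    w <- external_weights[[dis]]
    w <- w[w$gene %in% rownames(x), , drop = FALSE]
    n_shared[dis] <- nrow(w)
    if (nrow(w) == 0L)
      stop("no genes shared between cohort and weight table '", dis, "'",
           call. = FALSE)
    score_by_thr <- lapply(thresholds, function(thr) score_samples(x, w, thr))
    for (sc in scales) {
      y <- pheno[[sc]]
      for (t in seq_along(thresholds)) {
        ev <- evaluate_score(y, score_by_thr[[t]], Xbase)
        rows[[length(rows) + 1L]] <- data.frame(
          disorder = dis, scale = sc, threshold = thresholds[t],
          n_genes = attr(score_by_thr[[t]], "n_genes") %||% 0L,
          r2 = unname(ev["r2"]), p = unname(ev["p"]))
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$fdrp <- NA_real_
  for (dis in names(external_weights))
    tab$fdrp[tab$disorder == dis] <- bh_fdr(tab$p[tab$disorder == dis])
  summ <- do.call(rbind, lapply(names(external_weights), function(dis) {
    do.call(rbind, lapply(scales, function(sc) {
      sub <- tab[tab$disorder == dis & tab$scale == sc, ]
      i <- which.min(sub$p)
      data.frame(disorder = dis, scale = sc, max_r2 = max(sub$r2),
                 min_p = sub$p[i], fdrp = sub$fdrp[i])
    }))
  }))
  structure(list(table = tab, summary = summ, thresholds = thresholds,
                 n_shared_genes = n_shared, mode = "external"),
            class = "ptrs_result")
}

#' @export
print.ptrs_result <- function(x, ...) {
  cat(sprintf("polytranscript risk scores (%s mode)\n", x$mode))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Read / write transcript weight tables
#'
#' Tab-separated with columns `gene_id`, `beta`, `p`, `source`.
#'
#' @param path file path.
#' @return `transcript_weights` data frame.
#' @export
read_weights <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "beta", "p")
  if (!all(need %in% names(tab)))
    stop("weight table needs columns gene_id, beta, p", call. = FALSE)
  out <- data.frame(gene = tab$gene_id, beta = tab$beta, p = tab$p,
                    constant = tab$constant %||% FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "source") <- tab$source[1] %||% NA_character_
  class(out) <- c("transcript_weights", "data.frame")
  out
}

#' @rdname read_weights
#' @param weights a `transcript_weights` table.
#' @export
write_weights <- function(weights, path) {
  tab <- data.frame(gene_id = weights$gene, beta = weights$beta, p = weights$p,
                    source = attr(weights, "source") %||% NA_character_)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
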