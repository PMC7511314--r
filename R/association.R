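## Negative-binomial association of CBCL syndrome t-scores with module
## eigengenes (and then with member genes of significant modules), adjusting
## for covariates and surrogate variables, with joint BH-FDR and Nagelkerke
## R-squared increments.

build_design <- function(pheno, covariate_names, svs) {
  covmat <- covariate_matrix(pheno, covariate_names)
  svmat <- NULL
  if (!is.null(svs)) {
    svmat <- if (inherits(svs, "surrogate_variables")) svs$sv else as.matrix(svs)
    check_alignment(pheno$sample_id, rownames(svmat), "surrogate variables")
  }
  X <- cbind(`(Intercept)` = rep(1, nrow(pheno)), covmat, svmat)
  if (qr(X)$rank < ncol(X))
    stop("covariate/SV design is rank deficient", call. = FALSE)
  X
}

scale_response <- function(pheno, scale, shift_floor, t_floor) {
  y <- pheno[[scale]]
  if (is.null(y)) stop("phenotype table lacks scale column: ", scale, call. = FALSE)
  if (shift_floor) y <- y - t_floor
  y
}

#' Associate module eigengenes with CBCL syndrome scales
#'
#' For every (scale, eigengene) pair, fits the NB2 regression of the t-score
#' on the eigengene plus covariates (and surrogate variables) against the
#' covariate-only null, recording the eigengene's Wald statistics and the
#' Nagelkerke R-squared increment.  BH-FDR is applied jointly across all
#' scale-by-module tests.
#'
#' @param me a [module_eigengenes()] object (or samples-by-modules matrix).
#' @param pheno phenotype data frame aligned with the eigengene rows.
#' @param covariate_names protected covariates (default age, sex, race, RIN).
#' @param svs optional [estimate_svs()] result (or samples-by-k matrix).
#' @param scales CBCL scales to test (default all eight).
#' @param shift_floor if TRUE, model `t-score - t_floor` instead of the raw
#'   t-score (sensitivity option; default FALSE models the score directly).
#' @param t_floor floor used when `shift_floor = TRUE`.
#' @return `association_table` data frame with columns `scale`, `unit`,
#'   `beta`, `se`, `z`, `p`, `fdrp`, `r2_nagelkerke`.
#' @export
associate_modules <- function(me, pheno,
                              covariate_names = c("age", "sex", "race", "rin"),
                              svs = NULL, scales = cbcl_scales(),
                              shift_floor = FALSE, t_floor = 50L) {
  eg <- if (inherits(me, "module_eigengenes")) me$eigengenes else as.matrix(me)
  check_alignment(pheno$sample_id, rownames(eg), "module eigengenes")
  Xbase <- build_design(pheno, covariate_names, svs)
  rows <- vector("list", length(scales) * ncol(eg))
  i <- 0L
  for (sc in scales) {
    y <- scale_response(pheno, sc, shift_floor, t_floor)
    null_fit <- fit_nb_glm(y, Xbase)
    for (m in colnames(eg)) {
      X <- cbind(Xbase[, 1L, drop = FALSE], ME = eg[, m],
                 Xbase[, -1L, drop = FALSE])
      fit <- fit_nb_glm(y, X)
      i <- i + 1L
      rows[[i]] <- data.frame(
        scale = sc, unit = m,
        beta = unname(fit$coefficients["ME"]), se = unname(fit$se["ME"]),
        z = unname(fit$z["ME"]), p = unname(fit$p["ME"]),
        r2_nagelkerke = nagelkerke_r2(fit, null_fit))
    }
  }
  tab <- do.call(rbind, rows)
  tab$fdrp <- bh_fdr(tab$p)
  tab <- tab[, c("scale", "unit", "beta", "se", "z", "p", "fdrp", "r2_nagelkerke")]
  class(tab) <- c("association_table", "data.frame")
  tab
}

#' Gene-level association within significant modules
#'
#' Restricted follow-up of [associate_modules()]: for each scale with at
#' least one significant module, tests only the member genes of that scale's
#' significant modules (standardized normalized expression as predictor),
#' with BH-FDR across exactly these tests.
#'
#' @param x normalized (log2-CPM) genes-by-samples matrix.
#' @param pheno phenotype data frame.
#' @param partition a [detect_modules()] partition aligned with rows of `x`.
#' @param significant_pairs data frame with columns `scale` and `unit`
#'   (module label, e.g. from the significant rows of the module table).
#' @param covariate_names,svs,shift_floor,t_floor as in [associate_modules()].
#' @return `association_table` data frame (adds a `module` column); empty
#'   when `significant_pairs` is empty.
#' @export
associate_genes <- function(x, pheno, partition, significant_pairs,
                            covariate_names = c("age", "sex", "race", "rin"),
                            svs = NULL, shift_floor = FALSE, t_floor = 50L) {
  empty <- data.frame(scale = character(), unit = character(),
                      module = character(), beta = numeric(), se = numeric(),
                      z = numeric(), p = numeric(), fdrp = numeric(),
                      r2_nagelkerke = numeric())
  class(empty) <- c("association_table", "data.frame")
  if (is.null(significant_pairs) || nrow(significant_pairs) == 0L) return(empty)
  labels <- if (inherits(partition, "module_partition")) partition$labels else partition
  check_alignment(pheno$sample_id, colnames(x), "expression matrix")
  Xbase <- build_design(pheno, covariate_names, svs)
  module_of <- stats::setNames(paste0("ME", labels), names(labels))
  rows <- list()
  for (sc in unique(significant_pairs$scale)) {
    mods <- unique(significant_pairs$unit[significant_pairs$scale == sc])
    genes <- names(labels)[module_of %in% mods]
    y <- scale_response(pheno, sc, shift_floor, t_floor)
    null_fit <- fit_nb_glm(y, Xbase)
    for (g in genes) {
      expr <- as.numeric(x[g, ])
      if (stats::sd(expr) == 0) next
      z <- (expr - mean(expr)) / stats::sd(expr)
      X <- cbind(Xbase[, 1L, drop = FALSE], gene = z, Xbase[, -1L, drop = FALSE])
      fit <- fit_nb_glm(y, X)
      rows[[length(rows) + 1L]] <- data.frame(
        scale = sc, unit = g, module = unname(module_of[g]),
        beta = unname(fit$coefficients["gene"]), se = unname(fit$se["gene"]),
        z = unname(fit$z["gene"]), p = unname(fit$p["gene"]),
        r2_nagelkerke = nagelkerke_r2(fit, null_fit))
    }
  }
  if (!length(rows)) return(empty)
  tab <- do.call(rbind, rows)
  tab$fdrp <- bh_fdr(tab$p)
  tab <- tab[, c("scale", "unit", "module", "beta", "se", "z", "p", "fdrp",
                 "r2_nagelkerke")]
  class(tab) <- c("association_table", "data.frame")
  tab
}

#' Z-score matrix of module associations
#'
#' Reshapes an [associate_modules()] table into the scales-by-modules Wald
#' Z-score matrix behind the usual association heat map.
#'
#' @param tab an `association_table` from [associate_modules()].
#' @return scales-by-modules numeric matrix.
#' @export
association_z_matrix <- function(tab) {
  scales <- unique(tab$scale); units <- unique(tab$unit)
  m <- matrix(NA_real_, length(scales), length(units),
              dimnames = list(scales, units))
  m[cbind(match(tab$scale, scales), match(tab$unit, units))] <- tab$z
  m
}
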