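## Surrogate variable analysis: estimate hidden confounders in expression
## data after protecting known covariates.  The number of surrogate variables
## is chosen by a permutation (Buja-Eyuboglu style) null on the residual
## singular value spectrum; the SVs themselves come from an iteratively
## re-weighted SVD in which genes are weighted by an empirical probability of
## being affected by the SVs but not by the protected covariates.

#' Choose the number of surrogate variables by permutation
#'
#' Residualizes the expression matrix on the protected covariates and compares
#' each residual singular value's share of variance against a null obtained by
#' permuting every gene's residuals independently across samples (and
#' re-residualizing, which preserves the degrees of freedom lost to the
#' design).  Counts the leading components whose variance share exceeds the
#' `1 - alpha` permutation quantile, stopping at the first failure.
#'
#' @param x genes-by-samples matrix, normalized (log) scale.
#' @param covariates samples-by-p matrix of protected covariates (no
#'   intercept; one is added).
#' @param n_permutations number of permutation resamples (default 20).
#' @param alpha per-component significance level (default 0.05).
#' @param seed optional seed for the permutations.
#' @return integer number of surrogate variables (possibly 0).
#' @export
estimate_num_sv <- function(x, covariates = NULL, n_permutations = 20L,
                            alpha = 0.05, seed = NULL) {
  n <- ncol(x)
  p_cov <- 1L + if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= p_cov + 2L)
    stop("too few samples relative to covariates to estimate surrogate variables",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  R <- residualize(x, covariates)
  d2 <- svd(R, nu = 0, nv = 0)$d^2
  if (sum(d2) < 1e-12) return(0L)  # x is an exact covariate fit
  obs <- d2 / sum(d2)
  n_comp <- min(n - p_cov, length(obs))
  null <- matrix(0, nrow = n_permutations, ncol = length(obs))
  for (b in seq_len(n_permutations)) {
    Rp <- t(apply(R, 1L, sample))
    Rp <- residualize(Rp, covariates)
    dp <- svd(Rp, nu = 0, nv = 0)$d^2
    null[b, ] <- dp / sum(dp)
  }
  k <- 0L
  for (i in seq_len(n_comp)) {
    thr <- stats::quantile(null[, i], probs = 1 - alpha, names = FALSE)
    if (obs[i] > thr) k <- k + 1L else break
  }
  k
}

## Empirical local false discovery rate of a p-value vector: pi0 from the
## upper half of the distribution, density from a histogram.  Degenerate in
## the right ways: all-small p -> lfdr ~ 0; uniform p -> lfdr ~ 1.
empirical_lfdr <- function(p, n_bins = 20L) {
  pi0 <- min(1, 2 * mean(p >= 0.5))
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(p, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  dens <- tabulate(bin, nbins = n_bins) / (length(p) / n_bins)
  pmin(pi0 / pmax(dens[bin], 1e-8), 1)
}

#' Estimate surrogate variables by iteratively re-weighted SVD
#'
#' Starting from the leading right singular vectors of the covariate
#' residuals, iterates: (1) per-gene moderated F p-values (limma) for the SV
#' block given the covariates and for the covariate block alone; (2) gene
#' weights `(1 - lfdr(p_sv)) * lfdr(p_cov)` — an empirical probability of
#' being SV-affected but covariate-unaffected; (3) SVD of the row-weighted
#' residual matrix.  Stops when the principal angle between successive SV
#' subspaces falls below `tol`.
#'
#' @param x genes-by-samples matrix, normalized scale.
#' @param covariates samples-by-p protected covariate matrix.
#' @param k number of surrogate variables (>= 1), typically from
#'   [estimate_num_sv()].
#' @param max_iter,tol iteration cap (50) and principal-angle tolerance (1e-6).
#' @return object of class `surrogate_variables`: list with `sv`
#'   (samples-by-k, unit-variance columns), `k`, `varexp` (non-increasing
#'   variance shares), `converged`, `iterations`.
#' @export
estimate_svs <- function(x, covariates = NULL, k = 1L, max_iter = 50L,
                         tol = 1e-6) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  R <- residualize(x, covariates)
  rk <- qr(R)$rank
  if (k > rk)
    stop("k = ", k, " exceeds the rank (", rk, ") of the covariate residuals",
         call. = FALSE)
  C <- cbind(rep(1, ncol(x)), covariates)
  sv <- svd(R)$v[, seq_len(k), drop = FALSE]
  converged <- FALSE
  iter <- 0L
  varexp <- rep(NA_real_, k)
  p_cov <- NULL
  if (!is.null(covariates)) {
    fit0 <- limma::lmFit(x, C)
    fit0 <- limma::eBayes(fit0)
    tab0 <- limma::topTable(fit0, coef = seq(2L, ncol(C)), number = Inf,
                            sort.by = "none")
    p_cov <- tab0$P.Value
  }
  for (iter in seq_len(max_iter)) {
    design <- cbind(C, sv)
    fit1 <- limma::eBayes(limma::lmFit(x, design))
    sv_cols <- seq(ncol(C) + 1L, ncol(design))
    p_sv <- limma::topTable(fit1, coef = sv_cols, number = Inf,
                            sort.by = "none")$P.Value
    w <- 1 - empirical_lfdr(p_sv)
    if (!is.null(p_cov)) w <- w * empirical_lfdr(p_cov)
    sw <- svd(R * w)
    sv_new <- sw$v[, seq_len(k), drop = FALSE]
    ## principal angles between the old and new SV subspaces
    qa <- qr.Q(qr(sv)); qb <- qr.Q(qr(sv_new))
    cosines <- pmin(svd(crossprod(qa, qb))$d, 1)
    angle <- max(acos(cosines))
    sv <- sv_new
    varexp <- (sw$d^2 / sum(sw$d^2))[seq_len(k)]
    if (angle < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("surrogate variable estimation did not converge in ", max_iter,
            " iterations")
  ## deterministic sign: largest-magnitude element of each SV is positive
  for (j in seq_len(k)) {
    i <- which.max(abs(sv[, j]))
    if (sv[i, j] < 0) sv[, j] <- -sv[, j]
  }
  ## unit variance without re-centering: residual right singular vectors are
  ## already (near-)centered and stay exactly orthogonal this way
  sv <- sweep(sv, 2L, apply(sv, 2L, stats::sd), "/")
  dimnames(sv) <- list(colnames(x), paste0("SV", seq_len(k)))
  structure(list(sv = sv, k = k, varexp = varexp, converged = converged,
                 iterations = iter),
            class = "surrogate_variables")
}

#' @export
print.surrogate_variables <- function(x, ...) {
  cat(sprintf("%d surrogate variable(s); converged: %s (%d iterations)\n",
              x$k, x$converged, x$iterations))
  cat("variance shares:", paste(signif(x$varexp, 3), collapse = ", "), "\n")
  invisible(x)
}
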