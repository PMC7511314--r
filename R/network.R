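## Weighted gene co-expression network: soft-thresholded adjacency,
## topological overlap, average-linkage module detection with a simplified
## tree cut (static cut + recursive gap splits + core filters + eigengene
## merging), and module eigengenes.

#' Soft-thresholded co-expression adjacency
#'
#' Pearson correlation across samples raised to a soft power:
#' `|cor|^power` (unsigned) or `((1 + cor)/2)^power` (signed), unit diagonal.
#'
#' @param x genes-by-samples matrix, log scale.
#' @param power positive soft-threshold exponent.
#' @param network_type `"unsigned"` (default) or `"signed"`.
#' @return genes-by-genes adjacency in `[0, 1]`.
#' @export
adjacency <- function(x, power = 6, network_type = c("unsigned", "signed")) {
  network_type <- match.arg(network_type)
  if (power < 1) stop("power must be >= 1", call. = FALSE)
  r <- suppressWarnings(stats::cor(t(x)))
  if (anyNA(r)) {
    bad <- rownames(x)[apply(x, 1L, stats::sd) == 0]
    stop("correlations undefined; constant gene(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  a <- if (network_type == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with connectivity `k` excluding the self-edge and `TOM_ii = 1`.  The
#' clustering dissimilarity is `1 - TOM`.
#'
#' @param a symmetric adjacency with entries in `[0, 1]` and unit diagonal.
#' @return TOM similarity matrix in `[0, 1]`.
#' @export
tom_similarity <- function(a) {
  if (!is.matrix(a) || nrow(a) != ncol(a))
    stop("adjacency must be a square matrix", call. = FALSE)
  if (max(abs(a - t(a))) > 1e-8)
    stop("adjacency must be symmetric", call. = FALSE)
  if (min(a) < -1e-10 || max(a) > 1 + 1e-10)
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  diag(a) <- 1
  k <- rowSums(a) - 1
  num <- a %*% a - a          # sum_u a_iu a_uj over u != i,j, plus a_ij
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  dimnames(tom) <- dimnames(a)
  tom
}

#' Pick the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, computes the connectivity distribution and the
#' R-squared of the regression of `log10 p(k)` on `log10 k` over connectivity
#' bins.  Chooses the smallest power reaching the target R-squared with a
#' negative slope, falling back to the best-fitting power.
#'
#' @param x genes-by-samples matrix, log scale.
#' @param powers candidate powers.
#' @param network_type passed to [adjacency()].
#' @param r2_target scale-free fit target (default 0.8).
#' @param n_bins connectivity histogram bins (default 10).
#' @return list with `power` and `fit_table`
#'   (`power`, `r_squared`, `slope`, `mean_k`, `median_k`, `max_k`).
#' @export
pick_soft_threshold <- function(x, powers = c(1:10, seq(12, 20, by = 2)),
                                network_type = "unsigned",
                                r2_target = 0.8, n_bins = 10L) {
  rows <- lapply(powers, function(p) {
    a <- adjacency(x, power = p, network_type = network_type)
    k <- rowSums(a) - 1
    fit <- scale_free_fit(k, n_bins)
    data.frame(power = p, r_squared = fit$r_squared, slope = fit$slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$r_squared >= r2_target & tab$slope < 0)
  chosen <- if (length(ok)) tab$power[ok[1L]] else tab$power[which.max(tab$r_squared)]
  list(power = chosen, fit_table = tab)
}

## R^2 and slope of log10 p(k) ~ log10 k over equal-width connectivity bins.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(list(r_squared = 0, slope = 0))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- findInterval(k, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mean_k <- vapply(seq_len(n_bins),
                   function(b) if (counts[b] > 0) mean(k[bin == b]) else NA_real_,
                   numeric(1))
  keep <- counts > 0 & mean_k > 0
  if (sum(keep) < 3L) return(list(r_squared = 0, slope = 0))
  lx <- log10(mean_k[keep])
  ly <- log10(counts[keep] / length(k))
  fit <- stats::lm(ly ~ lx)
  list(r_squared = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2L]))
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on the dissimilarity, cut
#' statically at a fraction of the maximum merge height, then refined by
#' recursive two-way splits of clusters whose split yields branches of at
#' least `min_module_size` separated by a height gap of at least `gap_min`.
#' Clusters below `min_module_size` are pruned to label 0.  When expression
#' is supplied, two core filters apply (clusters whose eigengene explains
#' less than `varexp_min` of module variance are dissolved; genes whose
#' module-eigengene correlation `|kME|` falls below `kme_min` are pruned) and
#' modules whose eigengenes correlate above `1 - merge_height` are merged.
#' Labels are relabelled 1..M by decreasing size.
#'
#' @param dissim symmetric dissimilarity in `[0, 1]` (typically `1 - TOM`).
#' @param x optional genes-by-samples expression matrix aligned with
#'   `dissim`; required for the eigengene-based core filters and merging.
#' @param min_module_size smallest retained module (default 30).
#' @param merge_height eigengene merge threshold: modules with eigengene
#'   correlation above `1 - merge_height` are merged (default 0.15).
#' @param cut_height static cut as a fraction of the maximum merge height
#'   (default 0.99).
#' @param gap_min minimum height gap for a recursive split (default 0.02).
#' @param kme_min,varexp_min core-filter thresholds (0.3 and 0.25).
#' @param max_external_kme_frac artefact guard: a cluster whose eigengene
#'   correlates above `kme_min` with more than this fraction of genes
#'   *outside* the cluster is dissolved — a matrix-wide (batch-like) factor,
#'   not a locally connected module (default 0.05).
#' @return object of class `module_partition`: list with `labels` (named
#'   integer vector, 0 = unassigned), `sizes`, `n_modules`.
#' @export
detect_modules <- function(dissim, x = NULL, min_module_size = 30L,
                           merge_height = 0.15, cut_height = 0.99,
                           gap_min = 0.02, kme_min = 0.3, varexp_min = 0.25,
                           max_external_kme_frac = 0.05) {
  if (!is.matrix(dissim) || nrow(dissim) != ncol(dissim))
    stop("dissimilarity must be a square matrix", call. = FALSE)
  if (max(abs(dissim - t(dissim))) > 1e-8)
    stop("dissimilarity must be symmetric", call. = FALSE)
  p <- nrow(dissim)
  gene_ids <- rownames(dissim) %||% sprintf("g%05d", seq_len(p))
  if (p < min_module_size) {
    warning("fewer genes than min_module_size; all genes left unassigned")
    labels <- stats::setNames(integer(p), gene_ids)
    return(new_module_partition(labels))
  }
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  h0 <- cut_height * max(hc$height)
  coarse <- stats::cutree(hc, h = h0)
  clusters <- split(seq_len(p), coarse)

  split_rec <- function(idx) {
    if (length(idx) < 2L * min_module_size) return(list(idx))
    hs <- stats::hclust(stats::as.dist(dissim[idx, idx, drop = FALSE]),
                        method = "average")
    labs <- stats::cutree(hs, k = 2)
    g1 <- idx[labs == 1L]; g2 <- idx[labs == 2L]
    hts <- sort(hs$height, decreasing = TRUE)
    gap <- hts[1L] - hts[2L]
    if (min(length(g1), length(g2)) >= min_module_size && gap >= gap_min)
      c(split_rec(g1), split_rec(g2))
    else list(idx)
  }
  clusters <- unlist(lapply(clusters, split_rec), recursive = FALSE)
  clusters <- clusters[vapply(clusters, length, 1L) >= min_module_size]

  labels <- stats::setNames(integer(p), gene_ids)
  for (m in seq_along(clusters)) labels[clusters[[m]]] <- m

  if (!is.null(x) && length(clusters)) {
    stopifnot(nrow(x) == p)
    labels <- apply_core_filters(x, labels, min_module_size, kme_min,
                                 varexp_min, max_external_kme_frac)
    labels <- merge_close_modules(x, labels, merge_height)
  } else if (is.null(x) && length(clusters) > 1L) {
    message("expression matrix not supplied; eigengene merge step skipped")
  }
  new_module_partition(relabel_by_size(labels))
}

apply_core_filters <- function(x, labels, min_module_size, kme_min, varexp_min,
                               max_external_kme_frac) {
  for (m in sort(unique(labels[labels > 0]))) {
    idx <- which(labels == m)
    me <- single_eigengene(x[idx, , drop = FALSE])
    if (me$varexp < varexp_min) { labels[idx] <- 0L; next }
    kme <- abs(suppressWarnings(drop(stats::cor(t(x[idx, , drop = FALSE]), me$me))))
    kme[is.na(kme)] <- 0
    labels[idx[kme < kme_min]] <- 0L
    if (sum(labels == m) < min_module_size) { labels[labels == m] <- 0L; next }
    ## a module driven by a matrix-wide artefact (e.g. a batch factor) shows
    ## diffuse eigengene connectivity to genes outside itself; a genuine
    ## co-expression module is locally connected
    ext <- which(labels != m)
    if (length(ext) >= min_module_size) {
      kme_ext <- abs(suppressWarnings(
        drop(stats::cor(t(x[ext, , drop = FALSE]), me$me))))
      kme_ext[is.na(kme_ext)] <- 0
      ## calibrated against the null rate of |cor| > kme_min at this sample
      ## size, so the guard only fires on clearly matrix-wide factors; any
      ## per-sample common-mode component (library-size composition) should
      ## be removed from the input beforehand (see center_samples())
      null_frac <- 2 * stats::pnorm(-kme_min * sqrt(ncol(x) - 1))
      if (mean(kme_ext > kme_min) > max(max_external_kme_frac, 3 * null_frac))
        labels[labels == m] <- 0L
    }
  }
  labels
}

merge_close_modules <- function(x, labels, merge_height) {
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2L) break
    mes <- vapply(mods, function(m)
      single_eigengene(x[labels == m, , drop = FALSE])$me, numeric(ncol(x)))
    cors <- stats::cor(mes)
    diag(cors) <- -Inf
    top <- which(cors == max(cors), arr.ind = TRUE)[1L, ]
    if (cors[top[1L], top[2L]] <= 1 - merge_height) break
    keep <- mods[min(top)]; lose <- mods[max(top)]
    labels[labels == lose] <- keep
  }
  labels
}

relabel_by_size <- function(labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) return(labels)
  sizes <- vapply(mods, function(m) sum(labels == m), 1L)
  first_idx <- vapply(mods, function(m) which(labels == m)[1L], 1L)
  ord <- order(-sizes, first_idx)
  out <- labels
  for (i in seq_along(ord)) out[labels == mods[ord[i]]] <- i
  out
}

new_module_partition <- function(labels) {
  mods <- sort(unique(labels[labels > 0]))
  sizes <- vapply(mods, function(m) sum(labels == m), 1L)
  names(sizes) <- if (length(mods)) paste0("ME", mods)
  structure(list(labels = labels, sizes = sizes, n_modules = length(mods)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module partition: %d modules over %d genes (%d unassigned)\n",
              x$n_modules, length(x$labels), sum(x$labels == 0)))
  if (x$n_modules) print(x$sizes)
  invisible(x)
}

## First principal component of a standardized module submatrix.
single_eigengene <- function(sub) {
  z <- t(scale(t(sub)))
  if (anyNA(z))
    stop("constant gene(s) inside a module: ",
         paste(utils::head(rownames(sub)[apply(sub, 1, stats::sd) == 0], 5),
               collapse = ", "), call. = FALSE)
  sv <- svd(t(z), nu = 1L, nv = 0L)
  me <- sv$u[, 1L]
  if (stats::cor(me, colMeans(z)) < 0) me <- -me
  list(me = me / stats::sd(me), varexp = sv$d[1L]^2 / sum(sv$d^2))
}

#' Module eigengenes
#'
#' Per module, the first right singular vector of the standardized module
#' submatrix, scaled to unit variance and signed so that its correlation with
#' the module's mean standardized expression is nonnegative.  The proportion
#' of module variance explained is reported.
#'
#' @param x genes-by-samples expression matrix (log scale).
#' @param partition a [detect_modules()] partition (or a named integer label
#'   vector aligned to rows of `x`).
#' @return object of class `module_eigengenes`: list with `eigengenes`
#'   (samples-by-M matrix, columns `ME1..MEM`) and `varexp`.
#' @export
module_eigengenes <- function(x, partition) {
  labels <- if (inherits(partition, "module_partition")) partition$labels else partition
  if (length(labels) != nrow(x))
    stop("partition and expression matrix disagree on gene count", call. = FALSE)
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no labelled modules", call. = FALSE)
  eg <- matrix(NA_real_, nrow = ncol(x), ncol = length(mods),
               dimnames = list(colnames(x), paste0("ME", mods)))
  varexp <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    idx <- which(labels == mods[i])
    if (length(idx) < 2L)
      stop("module ME", mods[i], " has fewer than 2 genes", call. = FALSE)
    res <- tryCatch(single_eigengene(x[idx, , drop = FALSE]),
                    error = function(e)
                      stop("module ME", mods[i], ": ", conditionMessage(e),
                           call. = FALSE))
    eg[, i] <- res$me
    varexp[i] <- res$varexp
  }
  structure(list(eigengenes = eg, varexp = varexp), class = "module_eigengenes")
}

#' @export
print.module_eigengenes <- function(x, ...) {
  cat(sprintf("module eigengenes: %d samples x %d modules\n",
              nrow(x$eigengenes), ncol(x$eigengenes)))
  cat("variance explained:", paste(signif(x$varexp, 3), collapse = ", "), "\n")
  invisible(x)
}
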