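## Hypergeometric over-representation of module members in GMT gene-set
## collections, BH-corrected within each module.

#' Read / write GMT gene-set collections
#'
#' GMT: one set per line, tab-separated fields `name`, `description`,
#' members.  Duplicate members within a set are stored once.
#'
#' @param path GMT file path.
#' @return object of class `gene_set_collection`: list with `sets` (named
#'   list of character vectors), `description` (named), `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("GMT format error at line ", i, ": fewer than 3 fields", call. = FALSE)
    nm <- fields[1L]
    if (nm %in% names(sets))
      stop("GMT format error: duplicated set name '", nm, "'", call. = FALSE)
    sets[[nm]] <- unique(fields[-(1:2)])
    descs[nm] <- fields[2L]
  }
  structure(list(sets = sets, description = descs, source = path),
            class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection a `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]] %||% "", collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of a module in gene sets
#'
#' Per set: overlap `k` with the module, upper-tail hypergeometric
#' `P(X >= k)` with the universe as population, the set's universe overlap as
#' successes and the module size as draws; BH-FDR across the sets tested for
#' this module.  Sets are intersected with the universe first; sets with
#' fewer than `min_set_size` or more than `max_set_size` universe members are
#' skipped.
#'
#' @param module_genes character vector of module member identifiers
#'   (must be a subset of `universe`).
#' @param collection a [read_gmt()] collection.
#' @param universe all genes eligible for membership (the retained,
#'   post-pruning gene list).
#' @param min_set_size,max_set_size set-size bounds after universe
#'   intersection (defaults 5 and 2000).
#' @return data frame with columns `set`, `overlap`, `set_size`,
#'   `module_size`, `p`, `fdrp`, ordered by `p`.
#' @export
enrich_module <- function(module_genes, collection, universe,
                          min_set_size = 5L, max_set_size = 2000L) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe is empty", call. = FALSE)
  if (!all(module_genes %in% universe))
    stop("module genes must be a subset of the universe", call. = FALSE)
  module_genes <- unique(module_genes)
  N <- length(universe); n_draw <- length(module_genes)
  rows <- list()
  for (nm in names(collection$sets)) {
    s <- intersect(collection$sets[[nm]], universe)
    K <- length(s)
    if (K < min_set_size || K > max_set_size) next
    k <- length(intersect(module_genes, s))
    p <- stats::phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      set = nm, overlap = k, set_size = K, module_size = n_draw, p = p)
  }
  if (!length(rows))
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), module_size = integer(),
                      p = numeric(), fdrp = numeric()))
  tab <- do.call(rbind, rows)
  tab$fdrp <- bh_fdr(tab$p)
  tab[order(tab$p), ]
}

#' Enrichment of every module in a partition
#'
#' Convenience wrapper running [enrich_module()] for each labelled module
#' with the partitioned gene list as universe.
#'
#' @param partition a [detect_modules()] partition.
#' @param collection a gene-set collection.
#' @param ... passed to [enrich_module()].
#' @return single data frame with a leading `module` column.
#' @export
enrich_all_modules <- function(partition, collection, ...) {
  labels <- partition$labels
  universe <- names(labels)
  mods <- sort(unique(labels[labels > 0]))
  out <- lapply(mods, function(m) {
    tab <- enrich_module(names(labels)[labels == m], collection, universe, ...)
    if (nrow(tab)) cbind(module = paste0("ME", m), tab) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(module = character(), set = character(),
                      overlap = integer(), set_size = integer(),
                      module_size = integer(), p = numeric(), fdrp = numeric())
  rownames(out) <- NULL
  out
}
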