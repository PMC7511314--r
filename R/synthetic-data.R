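## Synthetic cohort generator with planted ground truth.
##
## Emulates the statistical structure the downstream analysis assumes: two
## matched groups of school-age children, NB2-distributed gene counts driven
## by latent co-expression module factors, a hidden batch factor touching a
## fraction of genes, Dirichlet leukocyte mixtures, and CBCL-style syndrome
## t-scores floored at 50 and driven by a subset of module factors plus
## covariates.  Every planted structure is recorded so each downstream stage
## can be scored against truth.

#' Simulation configuration
#'
#' Builds and validates the configuration for [generate_cohort()].  Defaults
#' describe the package's reference cohort: 100 samples in two matched groups,
#' 3,000 genes of which 1,500 belong to 10 planted modules, NB2 dispersion
#' 0.2, five leukocyte types with blood-like Dirichlet concentrations, a
#' hidden batch factor with log-scale SD 0.5 on 30% of genes, and latent
#' t-score noise SD of 12 t-score units (which, after flooring at 50, yields a
#' realized t-score SD near 7, typical of clinically enriched CBCL samples).
#'
#' @param n_samples,n_genes,n_modules cohort dimensions.
#' @param module_sizes integer vector (length `n_modules`, each >= 2,
#'   sum <= `n_genes`); unassigned genes are background.
#' @param factor_loading_sd log-scale SD of the module-factor contribution to
#'   an assigned gene's log-mean.
#' @param nb_dispersion NB2 dispersion phi in `Var = mu + phi mu^2`.
#' @param n_celltypes,dirichlet_alpha leukocyte mixture dimensions and
#'   Dirichlet concentration vector (length `n_celltypes`).
#' @param batch_effect_sd log-scale SD of per-gene batch effects.
#' @param batch_gene_fraction fraction of genes the batch touches.
#' @param phenotype_effects named list, one entry per CBCL scale, each a data
#'   frame with columns `module` and `effect` (t-score units per factor SD).
#'   Defaults plant an attention-problems effect of module 1 sized for a
#'   latent R^2 of 0.15 and an aggression effect of module 2 sized for 0.10
#'   (see [effect_for_target_r2()]).
#' @param phenotype_noise_sd latent noise SD of the t-score linear predictor.
#' @param phenotype_covariate_effects named numeric vector with elements
#'   `age` (per year, centered at 9), `sex` and `group` (contrast-coded).
#' @param covariate_effect_sd SD of per-gene RIN effects on the log-mean.
#' @param baseline_log_mean,baseline_log_sd distribution of per-gene baseline
#'   log-means.
#' @param t_floor CBCL t-score floor (50).
#' @param include_signature_genes if TRUE, a block of leukocyte-signature
#'   genes (see [simulate_signature()]) mixed according to the cohort's true
#'   cell proportions is appended to the count matrix, so that deconvolution
#'   can be exercised end-to-end on the cohort itself.  Off by default: the
#'   appended genes are correlated through the mixing proportions, which the
#'   plain planted-module structure deliberately avoids.
#' @param seed integer seed; all generator randomness derives from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 100L,
                              n_genes = 3000L,
                              n_modules = 10L,
                              module_sizes = NULL,
                              factor_loading_sd = 1.0,
                              nb_dispersion = 0.2,
                              n_celltypes = 5L,
                              dirichlet_alpha = NULL,
                              batch_effect_sd = 0.5,
                              batch_gene_fraction = 0.3,
                              phenotype_effects = NULL,
                              phenotype_noise_sd = 12,
                              phenotype_covariate_effects = c(age = 0.2, sex = 1.0, group = 4.0),
                              covariate_effect_sd = 0.05,
                              baseline_log_mean = log(150),
                              baseline_log_sd = 1.0,
                              t_floor = 50L,
                              include_signature_genes = FALSE,
                              seed = 1L) {
  if (n_samples < 2) stop_config("n_samples", "must be >= 2")
  if (n_genes < 1) stop_config("n_genes", "must be >= 1")
  if (n_modules < 0) stop_config("n_modules", "must be >= 0")
  if (is.null(module_sizes))
    module_sizes <- if (n_modules > 0)
      round(seq(60, 240, length.out = n_modules)) else integer()
  module_sizes <- as.integer(module_sizes)
  if (length(module_sizes) != n_modules)
    stop_config("module_sizes", "must have one size per module")
  if (n_modules > 0 && any(module_sizes < 2))
    stop_config("module_sizes", "must all be >= 2")
  if (sum(module_sizes) > n_genes)
    stop_config("module_sizes", "must sum to at most n_genes")
  if (factor_loading_sd < 0) stop_config("factor_loading_sd", "must be >= 0")
  if (nb_dispersion < 0) stop_config("nb_dispersion", "must be >= 0")
  if (is.null(dirichlet_alpha))
    dirichlet_alpha <- c(22, 12, 3.2, 2, 0.8)[seq_len(n_celltypes)]
  if (length(dirichlet_alpha) != n_celltypes || any(dirichlet_alpha <= 0) ||
      anyNA(dirichlet_alpha))
    stop_config("dirichlet_alpha", "must be a positive vector of length n_celltypes")
  if (batch_effect_sd < 0) stop_config("batch_effect_sd", "must be >= 0")
  if (batch_gene_fraction < 0 || batch_gene_fraction > 1)
    stop_config("batch_gene_fraction", "must lie in [0, 1]")
  if (phenotype_noise_sd < 0) stop_config("phenotype_noise_sd", "must be >= 0")
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_modules = as.integer(n_modules), module_sizes = module_sizes,
              factor_loading_sd = factor_loading_sd, nb_dispersion = nb_dispersion,
              n_celltypes = as.integer(n_celltypes), dirichlet_alpha = dirichlet_alpha,
              batch_effect_sd = batch_effect_sd,
              batch_gene_fraction = batch_gene_fraction,
              phenotype_noise_sd = phenotype_noise_sd,
              phenotype_covariate_effects = phenotype_covariate_effects,
              covariate_effect_sd = covariate_effect_sd,
              baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
              t_floor = as.integer(t_floor),
              include_signature_genes = isTRUE(include_signature_genes),
              seed = as.integer(seed))
  if (is.null(phenotype_effects)) {
    phenotype_effects <- list()
    if (n_modules >= 1)
      phenotype_effects$attention_problems <-
        data.frame(module = 1L, effect = effect_for_target_r2(0.15, cfg))
    if (n_modules >= 2)
      phenotype_effects$aggressive_behavior <-
        data.frame(module = 2L, effect = effect_for_target_r2(0.10, cfg))
  }
  bad_scale <- setdiff(names(phenotype_effects), cbcl_scales())
  if (length(bad_scale))
    stop_config("phenotype_effects", paste("names unknown scales:",
                                           paste(bad_scale, collapse = ", ")))
  for (sc in names(phenotype_effects)) {
    eff <- phenotype_effects[[sc]]
    if (!all(c("module", "effect") %in% names(eff)))
      stop_config("phenotype_effects", "entries need 'module' and 'effect' columns")
    if (any(eff$module < 1 | eff$module > n_modules))
      stop_config("phenotype_effects", "references a module that does not exist")
  }
  cfg$phenotype_effects <- phenotype_effects
  structure(cfg, class = "simulation_config")
}

#' Effect size for a target latent R-squared
#'
#' Analytic signal-to-noise mapping for planted phenotype effects: returns the
#' per-factor-SD effect (t-score units) for which the module factor explains
#' `r2` of the variance of the latent (pre-floor) t-score linear predictor,
#' given the configured noise and covariate effects.
#'
#' @param r2 target latent R-squared in (0, 1).
#' @param config a `simulation_config` (or list carrying
#'   `phenotype_noise_sd` and `phenotype_covariate_effects`).
#' @return positive effect size.
#' @export
effect_for_target_r2 <- function(r2, config) {
  stopifnot(r2 > 0, r2 < 1)
  ce <- config$phenotype_covariate_effects
  ## Var(U(6,12)) = 3; sex and group are balanced binaries with variance 1/4.
  cov_var <- sum(c(ce["age"]^2 * 3, ce["sex"]^2 * 0.25, ce["group"]^2 * 0.25),
                 na.rm = TRUE)
  sqrt(r2 / (1 - r2) * (config$phenotype_noise_sd^2 + cov_var))
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

rtruncnorm_interval <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= lower | out >= upper))
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

#' Generate a synthetic cohort with planted truth
#'
#' Draws covariates (age ~ U(6,12), sex and race balanced binaries,
#' RIN ~ N(8.75, 0.5) truncated to (6,10)), standard-normal module factors,
#' gene loadings of random sign with magnitude
#' `factor_loading_sd * |N(1, 0.25)|`, a standard-normal hidden batch score
#' with per-gene multiplicative (log-scale) effects on a random subset of
#' genes, and NB2 counts with log-mean
#' `baseline + loading * factor + batch effect + RIN effect`.
#' Phenotypes come from [plant_phenotypes()]; Dirichlet leukocyte proportions
#' are recorded as truth for the deconvolution stage.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_cohort`: a list with `counts`
#'   (genes-by-samples integer matrix, raw-counts scale), `phenotypes`
#'   (data frame), `truth_modules` (named integer vector, 0 = background),
#'   `truth_factors`, `truth_loadings`, `truth_proportions`, `truth_batch`,
#'   `truth_batch_genes`, and the `config` used.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("config must be built by simulation_config()", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_genes
  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_ids <- sprintf("g%05d", seq_len(p))

  group <- rep(c("typical", "case"), length.out = n)
  age <- stats::runif(n, 6, 12)
  sex <- stats::rbinom(n, 1, 0.5)
  race <- stats::rbinom(n, 1, 0.5)
  rin <- rtruncnorm_interval(n, 8.75, 0.5, 6, 10)
  medicated <- ifelse(group == "case", stats::rbinom(n, 1, 0.22), 0L)

  M <- config$n_modules
  truth_modules <- integer(p)
  if (M > 0)
    truth_modules[seq_len(sum(config$module_sizes))] <-
      rep(seq_len(M), times = config$module_sizes)
  names(truth_modules) <- gene_ids

  factors <- matrix(stats::rnorm(n * max(M, 1L)), nrow = n)
  factors <- factors[, seq_len(M), drop = FALSE]
  dimnames(factors) <- list(sample_ids, if (M > 0) paste0("factor", seq_len(M)))

  loadings <- numeric(p)
  in_module <- truth_modules > 0
  ## predominantly positive loadings: module genes are mostly co-regulated in
  ## the same direction, so the module mean expression tracks the factor and
  ## the eigengene orientation is meaningful
  loadings[in_module] <- sample(c(-1, 1), sum(in_module), replace = TRUE,
                                prob = c(0.2, 0.8)) *
    config$factor_loading_sd * abs(stats::rnorm(sum(in_module), 1, 0.25))
  names(loadings) <- gene_ids

  baseline <- stats::rnorm(p, config$baseline_log_mean, config$baseline_log_sd)
  n_batch <- round(config$batch_gene_fraction * p)
  batch_genes <- sort(sample.int(p, n_batch))
  batch_effect <- numeric(p)
  batch_effect[batch_genes] <- stats::rnorm(n_batch, 0, config$batch_effect_sd)
  truth_batch <- stats::rnorm(n)
  names(truth_batch) <- sample_ids
  rin_effect <- stats::rnorm(p, 0, config$covariate_effect_sd)

  logmu <- matrix(baseline, nrow = p, ncol = n)
  if (M > 0) {
    signal <- matrix(0, nrow = p, ncol = n)
    signal[in_module, ] <- loadings[in_module] *
      t(factors[, truth_modules[in_module], drop = FALSE])
    logmu <- logmu + signal
  }
  logmu <- logmu + outer(batch_effect, truth_batch) +
    outer(rin_effect, rin - 8.75)
  mu <- pmin(exp(logmu), 1e7)
  counts <- if (config$nb_dispersion > 0) {
    matrix(stats::rnbinom(p * n, mu = mu, size = 1 / config$nb_dispersion),
           nrow = p)
  } else {
    matrix(stats::rpois(p * n, lambda = mu), nrow = p)
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  expr_scale(counts) <- "raw_counts"

  proportions <- rdirichlet(n, config$dirichlet_alpha)
  dimnames(proportions) <- list(sample_ids,
                                default_celltype_names(config$n_celltypes))

  signature <- NULL
  if (config$include_signature_genes) {
    signature <- simulate_signature(seed = derive_seed(config$seed, 11L))
    mix <- generate_mixture(signature, proportions, noise_sd = 1,
                            seed = derive_seed(config$seed, 12L))
    mix <- round(mix * 20)  # onto a count-like scale
    truth_modules <- c(truth_modules,
                       stats::setNames(integer(nrow(mix)), rownames(mix)))
    counts <- rbind(counts, mix)
    expr_scale(counts) <- "raw_counts"
  }

  covariates <- data.frame(sample_id = sample_ids, group = group, age = age,
                           sex = sex, race = race, rin = rin,
                           medicated = medicated, stringsAsFactors = FALSE)
  phenotypes <- plant_phenotypes(factors, config, covariates = covariates)

  structure(list(counts = counts, phenotypes = phenotypes,
                 truth_modules = truth_modules, truth_factors = factors,
                 truth_loadings = loadings, truth_proportions = proportions,
                 truth_batch = truth_batch, truth_batch_genes = gene_ids[batch_genes],
                 signature = signature, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d genes x %d samples, %d planted modules\n",
              nrow(x$counts), ncol(x$counts), x$config$n_modules))
  cat(sprintf("  planted phenotype effects: %s\n",
              paste(names(x$config$phenotype_effects), collapse = ", ")))
  invisible(x)
}

default_celltype_names <- function(k) {
  base <- c("neutrophils", "lymphocytes", "monocytes", "eosinophils", "basophils")
  if (k <= length(base)) base[seq_len(k)] else
    c(base, sprintf("celltype%d", seq_len(k - length(base))))
}

#' Plant floored CBCL-style t-scores on latent factors
#'
#' Each syndrome scale is `max(t_floor, round(t_floor + lin))` where `lin`
#' sums the configured module-factor effects, centered covariate effects
#' (age, sex, group) and Gaussian noise.  Scores are integers bounded below by
#' the t-score floor.
#'
#' @param factors samples-by-modules latent factor matrix.
#' @param config a [simulation_config()].
#' @param covariates optional data frame with `sample_id`, `group`, `age`,
#'   `sex` (and any further columns, passed through); drawn from the config's
#'   marginals when omitted.
#' @return phenotype data frame: covariates plus the eight scale columns.
#' @export
plant_phenotypes <- function(factors, config, covariates = NULL) {
  n <- nrow(factors)
  for (sc in names(config$phenotype_effects)) {
    eff <- config$phenotype_effects[[sc]]
    if (any(eff$module > ncol(factors)))
      stop_config("phenotype_effects",
                  "references a factor column that does not exist")
  }
  set.seed(derive_seed(config$seed, 7L))
  if (is.null(covariates)) {
    covariates <- data.frame(
      sample_id = rownames(factors) %||% sprintf("S%03d", seq_len(n)),
      group = rep(c("typical", "case"), length.out = n),
      age = stats::runif(n, 6, 12),
      sex = stats::rbinom(n, 1, 0.5),
      race = stats::rbinom(n, 1, 0.5),
      rin = rtruncnorm_interval(n, 8.75, 0.5, 6, 10),
      stringsAsFactors = FALSE)
  }
  if (nrow(covariates) != n)
    stop("covariates and factors disagree on sample count", call. = FALSE)
  ce <- config$phenotype_covariate_effects
  cov_term <- rep(0, n)
  if (!is.na(ce["age"]))   cov_term <- cov_term + ce[["age"]] * (covariates$age - 9)
  if (!is.na(ce["sex"]))   cov_term <- cov_term + ce[["sex"]] * (covariates$sex - 0.5)
  if (!is.na(ce["group"])) cov_term <- cov_term +
      ce[["group"]] * ((covariates$group == "case") - 0.5)
  out <- covariates
  for (sc in cbcl_scales()) {
    lin <- cov_term
    eff <- config$phenotype_effects[[sc]]
    if (!is.null(eff))
      for (i in seq_len(nrow(eff)))
        lin <- lin + eff$effect[i] * factors[, eff$module[i]]
    lin <- lin + stats::rnorm(n, 0, config$phenotype_noise_sd)
    out[[sc]] <- as.integer(pmax(config$t_floor, round(config$t_floor + lin)))
  }
  out
}

#' Synthetic bulk mixtures from a signature matrix
#'
#' Each synthetic sample is `signature %*% t(proportions)` plus Gaussian
#' noise, clipped at zero — the linear mixing model that signature-based
#' deconvolution assumes.
#'
#' @param signature genes-by-celltypes linear-scale matrix.
#' @param proportions samples-by-celltypes matrix; rows must sum to 1.
#' @param noise_sd Gaussian noise SD (linear scale).
#' @param seed optional seed.
#' @return genes-by-samples matrix (raw linear scale).
#' @export
generate_mixture <- function(signature, proportions, noise_sd = 0, seed = NULL) {
  if (!is.matrix(signature) || !is.matrix(proportions))
    stop("signature and proportions must be matrices", call. = FALSE)
  if (ncol(signature) != ncol(proportions))
    stop("shape error: signature has ", ncol(signature),
         " cell types but proportions has ", ncol(proportions), call. = FALSE)
  if (any(abs(rowSums(proportions) - 1) > 1e-8))
    stop("proportions rows must sum to 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- signature %*% t(proportions)
  if (noise_sd > 0)
    m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow = nrow(m))
  m <- pmax(m, 0)
  rownames(m) <- rownames(signature)
  colnames(m) <- rownames(proportions) %||% sprintf("S%03d", seq_len(ncol(m)))
  expr_scale(m) <- "raw_counts"
  m
}

#' Synthetic leukocyte signature matrix
#'
#' A marker-block signature for tests and examples: every cell type has a set
#' of marker genes expressed at a much higher level in that type.  Labelled
#' synthetic; it stands in for externally supplied signature sets, which the
#' package deliberately does not bundle.
#'
#' @param n_genes,n_celltypes dimensions (markers split evenly).
#' @param seed seed.
#' @return genes-by-celltypes linear-scale matrix.
#' @export
simulate_signature <- function(n_genes = 60L, n_celltypes = 5L, seed = 1L) {
  set.seed(seed)
  base <- matrix(stats::runif(n_genes * n_celltypes, 5, 50), nrow = n_genes)
  marker_of <- rep(seq_len(n_celltypes), length.out = n_genes)
  for (k in seq_len(n_celltypes)) {
    idx <- which(marker_of == k)
    base[idx, k] <- base[idx, k] * stats::runif(length(idx), 10, 30)
  }
  dimnames(base) <- list(sprintf("sig%03d", seq_len(n_genes)),
                         default_celltype_names(n_celltypes))
  base
}
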