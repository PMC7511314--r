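# Shared fixtures, all generated in code.

covariate_names <- c("age", "sex", "race", "rin")

# Small cohort for fast unit tests.
small_cohort <- function(seed = 1, n_samples = 60, n_genes = 200, n_modules = 3,
                         module_sizes = c(50, 40, 30), ...) {
  generate_cohort(simulation_config(
    n_samples = n_samples, n_genes = n_genes, n_modules = n_modules,
    module_sizes = module_sizes, seed = seed, ...))
}

# Two perfectly separable correlation blocks plus optional noise genes:
# factor-driven rows with known within-block correlation.
block_matrix <- function(sizes = c(50, 40), n_noise = 0, n = 100,
                         within_cor = 0.9, seed = 1) {
  set.seed(seed)
  p <- sum(sizes) + n_noise
  x <- matrix(rnorm(p * n), nrow = p)
  lambda <- sqrt(within_cor / (1 - within_cor))
  start <- 0
  truth <- integer(p)
  for (b in seq_along(sizes)) {
    f <- rnorm(n)
    idx <- start + seq_len(sizes[b])
    x[idx, ] <- lambda * matrix(f, nrow = sizes[b], ncol = n, byrow = TRUE) +
      x[idx, ]
    truth[idx] <- b
    start <- start + sizes[b]
  }
  rownames(x) <- sprintf("g%04d", seq_len(p))
  colnames(x) <- sprintf("S%03d", seq_len(n))
  list(x = x, truth = truth)
}

# Simple agreement score between two partitions (adjusted Rand index comes
# from mclust where needed; this helper just aligns vectors).
label_vec <- function(partition) {
  if (inherits(partition, "module_partition")) partition$labels else partition
}

# Demographic table of the reference cohort study: group sizes 48/47,
# 22/23 males, 24/24 Caucasian.
demo_pheno <- function() {
  data.frame(
    sample_id = sprintf("S%03d", 1:95),
    group = rep(c("typical", "case"), times = c(48, 47)),
    sex = c(rep("male", 22), rep("female", 26), rep("male", 23), rep("female", 24)),
    race = c(rep("caucasian", 24), rep("other", 24), rep("caucasian", 24), rep("other", 23)),
    stringsAsFactors = FALSE)
}
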