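ptrs_cohort <- function(seed, effect = NULL, n_genes = 120, n_samples = 70) {
  eff <- if (is.null(effect)) list() else
    list(attention_problems = data.frame(module = 1, effect = effect))
  generate_cohort(simulation_config(
    n_samples = n_samples, n_genes = n_genes, n_modules = 2,
    module_sizes = c(30, 20), phenotype_effects = eff, seed = seed))
}

test_that("weight training finds a strongly causal gene and flags constants", {
  hits <- 0L
  for (s in 1:5) {
    co <- ptrs_cohort(s, effect = 9)
    norm <- cpm_normalize(co$counts)
    w <- train_weights(norm, co$phenotypes, "attention_problems",
                       covariate_names)
    # the most significant gene should belong to the causal module
    top <- w$gene[which.min(w$p)]
    if (co$truth_modules[top] == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
  # constant genes get weight 0, p 1, and a flag
  co <- ptrs_cohort(1)
  norm <- cpm_normalize(co$counts)
  norm[3, ] <- 2.5
  w <- train_weights(norm, co$phenotypes, "attention_problems", covariate_names)
  expect_equal(w$beta[3], 0)
  expect_equal(w$p[3], 1)
  expect_true(w$constant[3])
})

test_that("null weights have approximately uniform p-values", {
  # independent genes: correlated module members would clump their p-values
  # and break the distributional comparison without any miscalibration
  for (s in c(17, 19)) {
    co <- generate_cohort(simulation_config(
      n_samples = 80, n_genes = 150, n_modules = 0,
      phenotype_effects = list(), seed = s))
    norm <- cpm_normalize(co$counts)
    w <- train_weights(norm, co$phenotypes, "thought_problems", covariate_names)
    ks <- suppressWarnings(ks.test(w$p, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("scoring is the thresholded weighted sum it claims to be", {
  x <- matrix(c(-1, 0, 1, 2, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("S1", "S2", "S3")))
  w <- data.frame(gene = c("gA", "gB"), beta = c(2, 5), p = c(0.01, 0.5))
  ctr <- c(gA = 0, gB = 2); sds <- c(gA = 1, gB = 1)
  s <- score_samples(x, w, p_threshold = 0.05, center = ctr, scale = sds)
  expect_equal(as.numeric(s), c(-2, 0, 2))   # only gA passes the threshold
  s_all <- score_samples(x, w, p_threshold = 1.0, center = ctr, scale = sds)
  expect_equal(attr(s_all, "n_genes"), 2L)   # threshold 1.0 keeps every gene
  # gene order cannot matter
  s_rev <- score_samples(x, w[2:1, ], p_threshold = 1.0, center = ctr, scale = sds)
  expect_equal(as.numeric(s_all), as.numeric(s_rev))
  # empty selection yields flagged zeros; missing genes are an error
  s0 <- score_samples(x, w, p_threshold = 0.001, center = ctr, scale = sds)
  expect_true(attr(s0, "empty"))
  expect_equal(as.numeric(s0), c(0, 0, 0))
  expect_error(score_samples(x[1, , drop = FALSE], w, 1, ctr, sds), "gB")
})

test_that("cross-validation is deterministic, stratified, and leak-free", {
  co <- ptrs_cohort(23, effect = 6)
  norm <- cpm_normalize(co$counts)
  cv1 <- crossvalidate_ptrs(norm, co$phenotypes, scales = "attention_problems",
                            covariate_names = covariate_names, seed = 7,
                            store_weights = TRUE)
  cv2 <- crossvalidate_ptrs(norm, co$phenotypes, scales = "attention_problems",
                            covariate_names = covariate_names, seed = 7)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$table$r2, cv2$table$r2, tolerance = 1e-12)
  # every fold contains both groups
  for (f in 1:5) {
    g <- co$phenotypes$group[cv1$folds == f]
    expect_identical(sort(unique(g)), c("case", "typical"))
  }
  # the fold-1 weights must equal weights recomputed on fold-1's training
  # samples alone: nothing from the withheld fold leaks into training
  train_ids <- co$phenotypes$sample_id[cv1$folds != 1]
  w_ref <- train_weights(norm, co$phenotypes, "attention_problems",
                         covariate_names, samples = train_ids)
  expect_equal(cv1$weights[["attention_problems.1"]]$beta, w_ref$beta,
               tolerance = 1e-12)
  # threshold grid contract and FDR coherence
  expect_identical(nrow(cv1$table), 6L)
  expect_true(all(cv1$table$fdrp >= cv1$table$p - 1e-12))
  expect_error(crossvalidate_ptrs(norm, co$phenotypes, thresholds = c(0.1, 1)),
               "length 6")
})

test_that("external weights reproduce a whole-sample no-CV evaluation", {
  co <- ptrs_cohort(31, effect = 6)
  norm <- cpm_normalize(co$counts)
  w <- train_weights(norm, co$phenotypes, "attention_problems", covariate_names)
  ext <- external_ptrs(norm, co$phenotypes, list(denovo = w),
                       covariate_names = covariate_names)
  # 48-test contract: 8 scales x 6 thresholds per disorder
  expect_identical(nrow(ext$table), 48L)
  expect_identical(unname(ext$n_shared_genes["denovo"]), nrow(norm))
  # one cell recomputed by hand must match exactly
  thr <- 0.1
  s <- score_samples(norm, w, thr)
  Xb <- cbind(1, covariate_matrix(co$phenotypes, covariate_names))
  Xs <- cbind(Xb[, 1, drop = FALSE], score = s, Xb[, -1])
  y <- co$phenotypes$attention_problems
  fit <- fit_nb_glm(y, Xs); null <- fit_nb_glm(y, Xb)
  row <- ext$table[ext$table$scale == "attention_problems" &
                     ext$table$threshold == thr, ]
  expect_equal(row$r2, nagelkerke_r2(fit, null), tolerance = 1e-10)
  expect_equal(row$p, unname(fit$p["score"]), tolerance = 1e-10)
})

test_that("external scores transfer when the causal module is shared", {
  co_a <- ptrs_cohort(41, effect = 8, n_samples = 80)
  co_b <- ptrs_cohort(42, effect = 8, n_samples = 80)  # same planted module 1
  norm_a <- cpm_normalize(co_a$counts)
  norm_b <- cpm_normalize(co_b$counts)
  w <- train_weights(norm_a, co_a$phenotypes, "attention_problems",
                     covariate_names)
  attr(w, "source") <- "cohortA"
  ext <- external_ptrs(norm_b, co_b$phenotypes, list(cohortA = w),
                       covariate_names = covariate_names)
  att <- ext$summary[ext$summary$scale == "attention_problems", ]
  other <- ext$summary[ext$summary$scale == "somatic_complaints", ]
  expect_lt(att$min_p, 0.05)
  expect_gt(att$max_r2, other$max_r2)
})
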