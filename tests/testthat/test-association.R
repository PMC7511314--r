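assoc_cohort <- function(seed, effect = 6) {
  generate_cohort(simulation_config(
    n_samples = 80, n_genes = 150, n_modules = 3, module_sizes = c(40, 30, 30),
    phenotype_effects = list(
      attention_problems = data.frame(module = 1, effect = effect)),
    seed = seed))
}

test_that("a planted module effect is the top association with the right sign", {
  hits_top <- 0L; hits_sign <- 0L
  for (s in 1:5) {
    co <- assoc_cohort(s)
    norm <- cpm_normalize(co$counts)
    me <- module_eigengenes(norm, co$truth_modules)
    tab <- associate_modules(me, co$phenotypes, covariate_names)
    top <- tab[which.min(tab$p), ]
    if (top$scale == "attention_problems" && top$unit == "ME1")
      hits_top <- hits_top + 1L
    # orientation: the fitted coefficient of the causal pair must carry the
    # planted (positive) effect modulo the eigengene's alignment with the
    # factor
    ori <- sign(cor(me$eigengenes[, "ME1"], co$truth_factors[, 1]))
    causal <- tab[tab$scale == "attention_problems" & tab$unit == "ME1", ]
    if (sign(causal$beta) == ori) hits_sign <- hits_sign + 1L
  }
  expect_gte(hits_top, 4L)
  expect_gte(hits_sign, 5L)
})

test_that("association tables carry coherent statistics", {
  co <- assoc_cohort(7)
  norm <- cpm_normalize(co$counts)
  me <- module_eigengenes(norm, co$truth_modules)
  tab <- associate_modules(me, co$phenotypes, covariate_names)
  expect_identical(nrow(tab), length(cbcl_scales()) * 3L)
  expect_equal(tab$z, tab$beta / tab$se, tolerance = 1e-10)
  expect_true(all(tab$fdrp >= tab$p - 1e-12))
  expect_true(all(tab$fdrp <= 1 & tab$fdrp >= 0))
  expect_true(all(tab$r2_nagelkerke >= 0 & tab$r2_nagelkerke <= 1))
})

test_that("permuted phenotypes are not declared significant", {
  co <- assoc_cohort(9)
  norm <- cpm_normalize(co$counts)
  me <- module_eigengenes(norm, co$truth_modules)
  frac_sig <- numeric(20)
  for (b in 1:20) {
    set.seed(b)
    ph <- co$phenotypes
    perm <- sample(nrow(ph))
    for (sc in cbcl_scales()) ph[[sc]] <- ph[[sc]][perm]
    tab <- associate_modules(me, ph, covariate_names,
                             scales = c("attention_problems", "social_problems"))
    frac_sig[b] <- mean(tab$fdrp < 0.05)
  }
  expect_lte(mean(frac_sig), 0.05)
})

test_that("alignment and rank-deficiency guards fire", {
  co <- assoc_cohort(3)
  norm <- cpm_normalize(co$counts)
  me <- module_eigengenes(norm, co$truth_modules)
  ph_bad <- co$phenotypes; ph_bad$sample_id <- rev(ph_bad$sample_id)
  expect_error(associate_modules(me, ph_bad, covariate_names), "aligned")
  # duplicating an eigengene as an extra covariate breaks the design rank
  expect_error(
    associate_modules(me, co$phenotypes, covariate_names,
                      svs = me$eigengenes[, "ME1", drop = FALSE],
                      scales = "attention_problems"),
    "rank deficient")
})

test_that("gene-level follow-up respects the test-counting contract", {
  co <- assoc_cohort(5)
  norm <- cpm_normalize(co$counts)
  part <- ptrsnet:::new_module_partition(co$truth_modules)
  sig <- data.frame(scale = c("attention_problems", "attention_problems",
                              "social_problems"),
                    unit = c("ME1", "ME2", "ME1"))
  tab <- associate_genes(norm, co$phenotypes, part, sig, covariate_names)
  expect_identical(nrow(tab), (40L + 30L) + 40L)
  expect_true(all(tab$module[tab$scale == "social_problems"] == "ME1"))
  # empty input yields an empty table, not an error
  none <- associate_genes(norm, co$phenotypes, part, sig[0, ], covariate_names)
  expect_identical(nrow(none), 0L)
})

test_that("causal-module genes are enriched among significant genes", {
  sig_or <- matrix(0, 2, 2)
  for (s in 1:6) {
    co <- assoc_cohort(20 + s, effect = 7)
    norm <- cpm_normalize(co$counts)
    part <- ptrsnet:::new_module_partition(co$truth_modules)
    pairs <- data.frame(scale = "attention_problems", unit = c("ME1", "ME2", "ME3"))
    tab <- associate_genes(norm, co$phenotypes, part, pairs, covariate_names)
    causal <- tab$module == "ME1"
    sig <- tab$fdrp < 0.05
    sig_or <- sig_or + table(factor(causal, c(FALSE, TRUE)),
                             factor(sig, c(FALSE, TRUE)))
  }
  or <- (sig_or[2, 2] * sig_or[1, 1]) / max(sig_or[2, 1] * sig_or[1, 2], 1)
  expect_gt(or, 1)
})

test_that("the Z-score matrix reshapes the association table faithfully", {
  co <- assoc_cohort(3)
  norm <- cpm_normalize(co$counts)
  me <- module_eigengenes(norm, co$truth_modules)
  tab <- associate_modules(me, co$phenotypes, covariate_names)
  zm <- association_z_matrix(tab)
  expect_identical(dim(zm), c(8L, 3L))
  i <- sample(nrow(tab), 1)
  expect_equal(zm[tab$scale[i], tab$unit[i]], tab$z[i])
})
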