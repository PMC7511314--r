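test_that("adjacency matches its defining formula", {
  set.seed(1)
  x <- matrix(rnorm(5 * 40), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("S", 1:40)))
  r <- cor(t(x))
  # power 1, unsigned: adjacency is |cor| exactly
  a1 <- adjacency(x, power = 1)
  expect_lt(max(abs(a1 - abs(r))), 1e-12)
  # per-entry brute force at power 6, both network types
  a6 <- adjacency(x, power = 6)
  s6 <- adjacency(x, power = 6, network_type = "signed")
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    expect_equal(a6[i, j], abs(r[i, j])^6, tolerance = 1e-12)
    expect_equal(s6[i, j], ((1 + r[i, j]) / 2)^6, tolerance = 1e-12)
  }
  # a perfectly anticorrelated pair has unsigned adjacency 1 at any power
  y <- rbind(g1 = 1:10, g2 = -(1:10))
  colnames(y) <- paste0("S", 1:10)
  expect_equal(adjacency(y, power = 7)["g1", "g2"], 1, tolerance = 1e-12)
  # constant genes are refused
  x[2, ] <- 3
  expect_error(adjacency(x, power = 6), "constant")
})

test_that("topological overlap matches hand evaluation and a triple loop", {
  # 3 nodes, all off-diagonal adjacency 0.5: TOM_12 = (0.25 + 0.5) / 1.5
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 0.5, tolerance = 1e-12)
  # no edges: off-diagonal TOM is 0
  tom_id <- tom_similarity(diag(4))
  expect_true(all(tom_id[upper.tri(tom_id)] == 0))
  # random valid adjacency against an explicit triple loop
  set.seed(2)
  r <- cor(matrix(rnorm(6 * 30), ncol = 6))
  a <- abs(r)^3; diag(a) <- 1
  tom <- tom_similarity(a)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    num <- sum(a[i, -c(i, j)] * a[-c(i, j), j]) + a[i, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    expect_equal(tom[i, j], num / (min(ki, kj) + 1 - a[i, j]),
                 tolerance = 1e-12)
  }
  expect_true(all(tom >= 0 & tom <= 1))
  expect_error(tom_similarity(matrix(runif(9), 3)), "symmetric")
})

test_that("scale-free fit matches an independent binned regression", {
  bl <- block_matrix(sizes = c(40, 30), n_noise = 30, seed = 3)
  pick <- pick_soft_threshold(bl$x, powers = c(1, 2, 4, 6))
  expect_true(pick$power >= 1 && is.finite(pick$power))
  # independent oracle for one row of the fit table
  a <- adjacency(bl$x, power = 4)
  k <- rowSums(a) - 1
  breaks <- seq(min(k), max(k), length.out = 11)
  bin <- findInterval(k, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  df <- do.call(rbind, lapply(1:10, function(b) {
    if (!sum(bin == b)) return(NULL)
    data.frame(lk = log10(mean(k[bin == b])),
               lp = log10(sum(bin == b) / length(k)))
  }))
  oracle <- summary(lm(lp ~ lk, df))$r.squared
  expect_equal(pick$fit_table$r_squared[pick$fit_table$power == 4], oracle,
               tolerance = 1e-10)
  # connectivity is non-increasing in the power since |cor| <= 1
  k2 <- rowSums(adjacency(bl$x, power = 2)) - 1
  k6 <- rowSums(adjacency(bl$x, power = 6)) - 1
  expect_true(all(k6 <= k2 + 1e-12))
})

test_that("well-separated blocks are recovered exactly and noise pruned", {
  skip_if_not_installed("mclust")
  bl <- block_matrix(sizes = c(50, 40), n_noise = 60, n = 100,
                     within_cor = 0.9, seed = 4)
  tom <- tom_similarity(adjacency(bl$x, power = 6))
  part <- detect_modules(1 - tom, x = bl$x, min_module_size = 20)
  expect_identical(part$n_modules, 2L)
  # block recovery is perfect
  expect_equal(mclust::adjustedRandIndex(
    part$labels[bl$truth > 0], bl$truth[bl$truth > 0]), 1)
  # >= 90% of pure-noise genes are left unassigned
  expect_gte(mean(part$labels[bl$truth == 0] == 0), 0.9)
  # labels ordered by decreasing size
  expect_true(all(diff(part$sizes) <= 0))
  # determinism
  part2 <- detect_modules(1 - tom, x = bl$x, min_module_size = 20)
  expect_identical(part$labels, part2$labels)
})

test_that("anticorrelated halves of one block stay in one unsigned module", {
  set.seed(9)
  n <- 80; f <- rnorm(n)
  x <- rbind(3 * matrix(f, 30, n, byrow = TRUE),
             -3 * matrix(f, 30, n, byrow = TRUE)) + matrix(rnorm(60 * n), 60)
  dimnames(x) <- list(sprintf("g%03d", 1:60), sprintf("S%03d", 1:n))
  tom <- tom_similarity(adjacency(x, power = 6))
  part <- detect_modules(1 - tom, x = x, min_module_size = 20)
  expect_identical(part$n_modules, 1L)
  expect_gte(mean(part$labels == 1), 0.9)
})

test_that("module eigengenes agree with an independent SVD oracle", {
  bl <- block_matrix(sizes = c(40, 30), n = 60, seed = 5)
  labels <- setNames(bl$truth, rownames(bl$x))
  me <- module_eigengenes(bl$x, labels)
  expect_identical(colnames(me$eigengenes), c("ME1", "ME2"))
  for (m in 1:2) {
    z <- t(scale(t(bl$x[bl$truth == m, ])))
    pc <- svd(t(z))$u[, 1]            # independent full SVD
    pc <- pc / sd(pc)
    got <- me$eigengenes[, m]
    expect_lt(min(max(abs(got - pc)), max(abs(got + pc))), 1e-10)
  }
  # unit variance and nonnegative correlation with module mean expression
  expect_equal(apply(me$eigengenes, 2, sd), c(ME1 = 1, ME2 = 1),
               tolerance = 1e-12)
  for (m in 1:2) {
    z <- t(scale(t(bl$x[bl$truth == m, ])))
    expect_gte(cor(me$eigengenes[, m], colMeans(z)), 0)
  }
})

test_that("eigengene edge cases behave as specified", {
  n <- 40
  shared <- rnorm(n)
  x <- matrix(rep(shared, each = 5), nrow = 5) # identical genes
  dimnames(x) <- list(paste0("g", 1:5), paste0("S", 1:n))
  me <- module_eigengenes(x, setNames(rep(1L, 5), rownames(x)))
  expect_equal(me$varexp[["ME1"]], 1, tolerance = 1e-12)
  expect_equal(unname(me$eigengenes[, 1]),
               as.vector(scale(shared)), tolerance = 1e-10)
  # flipping the sign of every gene leaves |cor(ME, profile)| unchanged
  me_flip <- module_eigengenes(-x, setNames(rep(1L, 5), rownames(x)))
  expect_equal(abs(cor(me_flip$eigengenes[, 1], shared)),
               abs(cor(me$eigengenes[, 1], shared)), tolerance = 1e-10)
  # constant genes are an error naming the module
  x[2, ] <- 7
  expect_error(module_eigengenes(x, setNames(rep(1L, 5), rownames(x))), "ME1")
})

test_that("no random unit projection beats the eigengene's variance share", {
  bl <- block_matrix(sizes = c(30), n = 50, seed = 6)
  sub <- bl$x[bl$truth == 1, ]
  z <- t(scale(t(sub)))
  me <- module_eigengenes(sub, setNames(rep(1L, 30), rownames(sub)))
  total <- sum(z^2)
  set.seed(7)
  for (i in 1:100) {
    w <- rnorm(30); w <- w / sqrt(sum(w^2))
    proj <- drop(w %*% z)
    expect_lte(sum(proj^2) / total, me$varexp[["ME1"]] + 1e-10)
  }
})
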