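test_that("count matrices round-trip exactly through both dialects", {
  x <- matrix(c(0, 5, 12, 3, 0, 7), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("S1", "S2")))
  expr_scale(x) <- "raw_counts"
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_counts(x, tsv, "tsv")
  y <- read_counts(tsv, "tsv")
  expect_identical(unname(y), unname(x))
  expect_identical(dimnames(y), dimnames(x))
  expect_identical(expr_scale(y), "raw_counts")

  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_counts(x, mtx, "mtx")
  z <- read_counts(mtx, "mtx")
  expect_equal(unname(z), unname(x))
  expect_identical(dimnames(z), dimnames(x))
})

test_that("malformed count input is rejected", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1\tS2", "gA\t1\t2", "gA\t3\t4"), tsv)
  expect_error(read_counts(tsv, "tsv"), "duplicated gene")
  writeLines(c("gene_id\tS1\tS2", "gA\t1\t2", "gB\t-3\t4"), tsv)
  expect_error(read_counts(tsv, "tsv"), "negative")
})

test_that("low-abundance filtering matches hand enumeration and is idempotent", {
  # libraries: 100, 200, 400, 1000; CPM threshold 1e4 with min_cpm chosen so
  # that survival can be enumerated by hand
  x <- matrix(c(
    0,  0,  0,   0,    # all-zero: always removed for min_cpm > 0
    1,  0,  0,   0,    # CPM 1e4,0,0,0        -> passes in 1/4 samples
    2,  4,  8,  20,    # CPM 2e4,2e4,2e4,2e4  -> passes in 4/4
    0,  4,  0,  30,    # CPM 0,2e4,0,3e4      -> passes in 2/4
    97, 192, 392, 950  # remainder            -> passes everywhere
  ), nrow = 5, byrow = TRUE,
  dimnames = list(paste0("g", 1:5), paste0("S", 1:4)))
  expr_scale(x) <- "raw_counts"
  out <- filter_low_abundance(x, min_cpm = 1e4, min_fraction = 0.5)
  expect_identical(rownames(out), c("g3", "g4", "g5"))
  # idempotent on its own output
  out2 <- filter_low_abundance(out, min_cpm = 1e4, min_fraction = 0.5)
  expect_identical(out2, out)
  # min_cpm = 0 keeps everything
  expect_identical(rownames(filter_low_abundance(x, min_cpm = 0)), rownames(x))
  # all-zero gene removed for any positive threshold
  expect_false("g1" %in% rownames(filter_low_abundance(x, min_cpm = 1e-6)))
})

test_that("log2-CPM normalization matches the per-entry formula", {
  set.seed(42)
  x <- matrix(rpois(50, 40) + 1, nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("S", 1:5)))
  expr_scale(x) <- "raw_counts"
  out <- cpm_normalize(x)
  brute <- x
  for (j in 1:5) for (i in 1:10)
    brute[i, j] <- log2(x[i, j] / sum(x[, j]) * 1e6 + 1)
  expect_equal(unname(out), unname(brute), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(expr_scale(out), "log2_cpm")

  # a count of 1000 in a library of 1e6 is CPM 1000
  y <- matrix(c(1000, 1e6 - 1000), nrow = 2,
              dimnames = list(c("g1", "g2"), "S1"))
  expr_scale(y) <- "raw_counts"
  expect_equal(cpm_normalize(y)["g1", "S1"], log2(1001))

  # doubling all counts of a sample leaves its CPMs unchanged
  x2 <- x; x2[, 3] <- 2 * x[, 3]
  expr_scale(x2) <- "raw_counts"
  expect_equal(cpm_normalize(x2)[, 3], out[, 3], tolerance = 1e-12)
})

test_that("group comparison reproduces the cohort demographic statistics", {
  ph <- demo_pheno()
  cmp <- compare_groups(ph, "group", categorical_vars = c("sex", "race"))
  chi_sex <- cmp$statistic[cmp$variable == "sex"]
  chi_race <- cmp$statistic[cmp$variable == "race"]
  expect_equal(round(chi_sex, 3), 0.009)
  expect_lt(chi_race, 0.001)
  # identical groups give zero statistics
  ph2 <- data.frame(sample_id = sprintf("S%d", 1:40),
                    group = rep(c("a", "b"), each = 20),
                    v = rep(rnorm(20), 2),
                    c = rep(rep(c("x", "y"), each = 10), 2))
  cmp2 <- compare_groups(ph2, "group", "v", "c")
  expect_equal(cmp2$statistic, c(0, 0), tolerance = 1e-12)
})

test_that("Yates chi-squared equals the closed-form 2x2 formula", {
  set.seed(7)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    hand <- n * max(abs(a * d - b * c) - n / 2, 0)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    got <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))$statistic
    expect_equal(unname(got), hand, tolerance = 1e-12)
  }
})

test_that("annotation summary reports rounded percentages", {
  s <- annotation_summary(14318, 11529)
  expect_equal(s$percent, 81)
  expect_error(annotation_summary(10, 11), "invalid")
})
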