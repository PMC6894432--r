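test_that("TMM factors are 1 for identical and purely scaled libraries", {
  m <- matrix(rpois(200, 50) + 1, 100, 2,
              dimnames = list(sprintf("g%03d", 1:100), c("A", "B")))
  m[, 2] <- m[, 1]
  em <- expression_matrix(m, "mRNA", "counts")
  f <- tmm_factors(em)
  expect_equal(unname(as.numeric(f)), c(1, 1), tolerance = 1e-12)

  # B = 2 x A: composition unchanged, so after CPM scaling with the
  # factors every gene matches across samples
  m2 <- cbind(A = m[, 1], B = 2 * m[, 1])
  em2 <- expression_matrix(m2, "mRNA", "counts")
  f2 <- tmm_factors(em2)
  cpm <- unclass(to_log2cpm(em2, f2, prior = 0.5))
  # equal up to the pseudo-count, whose share halves in the larger library
  expect_equal(cpm[, "A"], cpm[, "B"], tolerance = 0.02)
  expect_equal(unname(f2["A"] / f2["B"]), 1, tolerance = 0.01)
})

test_that("TMM factors multiply to one and flag all-zero samples", {
  set.seed(11)
  m <- matrix(rnbinom(300, mu = 60, size = 10), 100, 3,
              dimnames = list(sprintf("g%03d", 1:100), c("A", "B", "C")))
  m[1:20, 2] <- m[1:20, 2] * 8   # composition shift
  em <- expression_matrix(m, "mRNA", "counts")
  f <- tmm_factors(em)
  expect_equal(prod(f), 1, tolerance = 1e-12)
  m0 <- m; m0[, 3] <- 0
  expect_error(tmm_factors(expression_matrix(m0, "mRNA", "counts")), "C")
})

test_that("TMM agrees with the edgeR reference on a composition-shifted matrix", {
  set.seed(5)
  m <- matrix(rnbinom(500 * 4, mu = 100, size = 5), 500, 4,
              dimnames = list(sprintf("g%03d", 1:500), paste0("S", 1:4)))
  m[1:50, 3] <- m[1:50, 3] * 10
  ours <- tmm_factors(expression_matrix(m, "mRNA", "counts"),
                      ref_sample = "S1")
  theirs <- edgeR::calcNormFactors(m, method = "TMM", refColumn = 1)
  theirs <- theirs / exp(mean(log(theirs)))
  expect_equal(unname(as.numeric(ours)), unname(theirs), tolerance = 0.03)
})

test_that("log2-CPM matches its defining formula and is scale invariant", {
  m <- matrix(c(0, rep(100, 9)), 10, 1,
              dimnames = list(sprintf("g%02d", 1:10), "S"))
  em <- expression_matrix(m, "mRNA", "counts")
  v <- unclass(to_log2cpm(em, prior = 0.5))
  lib <- sum(m)
  expect_equal(unname(v[1, 1]), log2(0.5 / lib * 1e6))
  expect_equal(unname(v[2, 1]), log2(100.5 / lib * 1e6))
  # doubling all counts (and hence the library) leaves values unchanged
  # up to the pseudo-count's vanishing contribution
  em2 <- expression_matrix(2 * m, "mRNA", "counts")
  v2 <- unclass(to_log2cpm(em2, prior = 0.5))
  expect_equal(v2[2:10, ], v[2:10, ], tolerance = 5e-3)
  expect_identical(attr(to_log2cpm(em), "unit"), "log2CPM")
  expect_error(to_log2cpm(em, prior = 0), "prior")
})

test_that("paired test reproduces the closed-form t statistic and zero-variance rule", {
  clin <- clinical_table(data.frame(
    sample_id = c("t1", "n1", "t2", "n2", "t3", "n3", "t4", "n4"),
    patient_id = rep(paste0("p", 1:4), each = 2),
    condition = rep(c("tumor", "normal"), 4),
    pair_id = rep(paste0("p", 1:4), each = 2)))
  jit <- c(0.01, -0.01, 0.02, -0.02)
  vals <- rbind(
    gA = c(5, 5, 6, 6, 7, 7, 8, 8),                 # identical in all pairs
    gB = c(6 + jit[1], 5, 6 + jit[2], 5, 6 + jit[3], 5, 6 + jit[4], 5))
  colnames(vals) <- clin$sample_id
  em <- expression_matrix(vals, "mRNA", "log2CPM")
  expect_warning(de <- paired_de_test(em, clin), "zero-variance")
  expect_equal(de$log2fc[de$gene_id == "gA"], 0)
  expect_equal(de$p_value[de$gene_id == "gA"], 1)
  # hand-computed t for gB: differences 1 + jit
  d <- 1 + jit
  t_hand <- mean(d) / (sd(d) / 2)
  p_hand <- 2 * pt(-abs(t_hand), df = 3)
  expect_equal(de$log2fc[de$gene_id == "gB"], mean(d))
  expect_equal(de$p_value[de$gene_id == "gB"], p_hand)
  expect_lt(de$p_value[de$gene_id == "gB"], 0.05)
})

test_that("paired test rejects unpaired samples and planted DE genes are recovered", {
  co <- default_cohort(1)
  norm <- to_log2cpm(co$lncrna, tmm_factors(co$lncrna))
  clin_broken <- as.data.frame(co$clinical)
  clin_broken$pair_id[1] <- NA
  class(clin_broken) <- class(co$clinical)
  expect_error(paired_de_test(norm, clin_broken), "unpaired")

  sens <- vapply(1:3, function(s) {
    coS <- default_cohort(s)
    normS <- to_log2cpm(coS$lncrna, tmm_factors(coS$lncrna))
    de <- suppressWarnings(paired_de_test(normS, coS$clinical))
    sel <- select_de_genes(de, 0.01, 1)
    truth <- coS$truth$de$gene_id[coS$truth$de$role == "lncRNA"]
    mean(truth %in% sel)
  }, 0)
  expect_true(all(sens >= 0.8))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(benjamini_hochberg(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("DE selection applies strict thresholds and ignores gene order", {
  de <- data.frame(
    gene_id = sprintf("g%02d", 1:10),
    log2fc = c(1.5, 1.0, -2, 0.5, 3, -1.01, 0.99, 2, -0.2, 1.2),
    p_value = 0.001,
    fdr = c(0.005, 0.005, 0.005, 0.005, 0.02, 0.0099, 0.001, 0.01, 0.001,
            0.005))
  # passing: g01 (0.005, 1.5), g03 (0.005, -2), g06 (0.0099, -1.01), g10
  expect_equal(select_de_genes(de), c("g01", "g03", "g06", "g10"))
  # boundary: |lfc| = 1 exactly is excluded, fdr = 0.01 excluded
  expect_false("g02" %in% select_de_genes(de))
  expect_false("g08" %in% select_de_genes(de))
  shuffled <- de[sample(nrow(de)), ]
  expect_equal(select_de_genes(shuffled), select_de_genes(de))
})

test_that("top/bottom miRNA rule returns 2k genes with lexicographic ties", {
  de <- data.frame(gene_id = sprintf("m%02d", 1:30),
                   log2fc = seq(-3, 3, length.out = 30),
                   p_value = 0.5, fdr = 0.5)
  sel <- select_top_bottom_mirnas(de, k = 10)
  expect_length(sel, 20)
  expect_setequal(sel, de$gene_id[c(1:10, 21:30)])
  # tie at the boundary: lexicographically first kept
  de_tie <- data.frame(gene_id = c("mirB", "mirA", "mirC", "mirD"),
                       log2fc = c(2, 2, -1, -2), p_value = 0.5, fdr = 0.5)
  sel_tie <- select_top_bottom_mirnas(de_tie, k = 1)
  expect_true("mirA" %in% sel_tie)
  expect_false("mirB" %in% sel_tie)
  expect_length(select_top_bottom_mirnas(de_tie[1:2, ], k = 1), 2)
  expect_error(select_top_bottom_mirnas(de_tie, k = 3), ">= 6")
})
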