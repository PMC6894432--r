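test_that("co-expression network applies the inclusive 0.7 cutoff", {
  samples <- sprintf("s%02d", 1:40)
  set.seed(71)
  base <- rnorm(40)
  mk_pair <- function(target_r) {
    # construct a vector with (near-)exact sample correlation target_r
    resid <- residuals(lm(rnorm(40) ~ base))
    v <- target_r * scale(base)[, 1] +
      sqrt(1 - target_r^2) * scale(resid)[, 1]
    v
  }
  lnc <- rbind(L1 = base, L2 = mk_pair(0.71), L3 = mk_pair(0.69))
  colnames(lnc) <- samples
  mrna <- rbind(G1 = mk_pair(0.75), G2 = mk_pair(0.3))
  colnames(mrna) <- samples
  eml <- expression_matrix(lnc, "lncRNA", "log2CPM")
  emm <- expression_matrix(mrna, "mRNA", "log2CPM")
  net <- build_coexpression_network(eml, emm, pcc_min = 0.7)
  key <- paste(net$gene_a, net$gene_b)
  expect_true("L1 L2" %in% key)    # 0.71 present
  expect_false("L1 L3" %in% key)   # 0.69 absent
  expect_true("L1 G1" %in% key)
  expect_false("L1 G2" %in% key)
  expect_true(all(net$pcc >= 0.7))
  expect_true(all(net$gene_a != net$gene_b))
})

test_that("co-expression edges match hand-computed toy correlations", {
  samples <- paste0("s", 1:4)
  lnc <- rbind(L1 = c(1, 2, 3, 4), L2 = c(2, 4, 6, 8),
               L3 = c(4, 3, 2, 1))
  colnames(lnc) <- samples
  mrna <- rbind(G1 = c(1.1, 1.9, 3.2, 3.8))
  colnames(mrna) <- samples
  net <- build_coexpression_network(
    expression_matrix(lnc, "lncRNA", "log2CPM"),
    expression_matrix(mrna, "mRNA", "log2CPM"), pcc_min = 0.7)
  key <- paste(net$gene_a, net$gene_b)
  # by hand: cor(L1,L2)=1, cor(L1,L3)=-1, cor(L2,L3)=-1, cor(L1,G1)~0.99
  expect_setequal(key, c("L1 L2", "L1 G1", "L2 G1"))
  expect_error(build_coexpression_network(
    expression_matrix(lnc, "lncRNA", "log2CPM"),
    expression_matrix(mrna[, 1:3, drop = FALSE], "mRNA", "log2CPM")),
    "sample")
})

test_that("top-degree rule keeps ties and honours the ceiling", {
  mk_net <- function(degrees) {
    pairs <- do.call(rbind, lapply(seq_along(degrees), function(i)
      data.frame(lncrna_id = sprintf("L%02d", i),
                 mrna_id = sprintf("G%02d_%03d", i, seq_len(degrees[i])),
                 shared_mirnas = "")))
    class(pairs) <- c("cerna_pairs", "data.frame")
    build_cerna_network(pairs, include_mirna_nodes = FALSE)
  }
  net <- mk_net(10:1)
  expect_equal(top_degree_nodes(net, 0.2), c("L01", "L02"))
  net_tie <- mk_net(c(5, 5, 5, rep(1, 7)))
  expect_equal(top_degree_nodes(net_tie, 0.2), c("L01", "L02", "L03"))
  expect_length(top_degree_nodes(net, 1), 10)
})

test_that("candidate selection requires all three conditions", {
  pairs <- data.frame(
    lncrna_id = c(rep("L01", 5), rep("L02", 5), "L03"),
    mrna_id = sprintf("G%02d", 1:11), shared_mirnas = "")
  class(pairs) <- c("cerna_pairs", "data.frame")
  net <- build_cerna_network(pairs, include_mirna_nodes = FALSE)
  modules <- structure(list(assignment = c(
    L01 = "M1", L02 = "M2", L03 = "M1")), class = "module_set")
  sig <- data.frame(module = "M1", best_stage = "III", best_r = 0.5,
                    best_p = 0.001)
  coexp <- structure(data.frame(
    gene_a = c("L01", "L03"), gene_b = c("G01", "G99"),
    pcc = c(0.8, 0.75), type = "lnc-mrna"),
    class = c("coexpression_network", "data.frame"))
  rep_ <- select_candidates(net, modules, sig, coexp, fraction = 0.34)
  # L01: hub + M1 + coexp edge -> candidate. L02: hub but M2 -> excluded.
  # L03: M1 + coexp but degree 1 below the top-34% boundary of (5,5,1).
  expect_equal(rep_$candidates$lncrna_id, "L01")
  # linked mRNA union with evidence labels
  tt <- candidate_target_table(rep_)
  expect_setequal(tt$mrna_id, c(sprintf("G%02d", 1:5)))
  expect_equal(tt$evidence[tt$mrna_id == "G01"], "both")
  expect_true(all(tt$evidence[tt$mrna_id != "G01"] == "cerna"))
  # empty significant set warns and returns an empty report
  expect_warning(
    r0 <- select_candidates(net, modules, sig[0, ], coexp, 0.34),
    "no TNM")
  expect_equal(nrow(r0$candidates), 0)
})

test_that("relaxing the degree fraction never shrinks the candidate set", {
  run <- default_run(1)
  res <- run$results
  sets <- lapply(c(0.1, 0.2, 0.5, 1), function(f)
    suppressWarnings(select_candidates(
      res$cerna$network, res$wgcna$modules, res$wgcna$significant,
      res$select$coexp, f))$candidates$lncrna_id)
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("planted candidates are recovered with at most two extras", {
  for (s in 1:3) {
    run <- default_run(s)
    truth <- run$results$cohort$truth
    cands <- run$results$select$report$candidates$lncrna_id
    expect_equal(sum(truth$candidates %in% cands), 8)
    expect_lte(sum(!cands %in% truth$candidates), 2)
  }
})

test_that("candidate-target table is deterministic and labels evidence", {
  run <- default_run(1)
  t1 <- candidate_target_table(run$results$select$report)
  t2 <- candidate_target_table(run$results$select$report)
  expect_identical(t1, t2)
  expect_true(all(t1$evidence %in% c("cerna", "coexp", "both")))
  expect_equal(attr(t1, "n_distinct_mrna"), length(unique(t1$mrna_id)))
})
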