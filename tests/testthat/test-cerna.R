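test_that("hypergeometric upper tail matches exhaustive enumeration for N <= 12", {
  max_err <- 0
  for (N in 1:12) for (n in 0:N) for (K in 0:N) {
    for (m in 0:min(K, n)) {
      p <- hypergeometric_upper_p(N, K, n, m)
      o <- oracle_hyper_enum(N, K, n, m)
      max_err <- max(max_err, abs(p - o))
    }
  }
  expect_lt(max_err, 1e-12)
})

test_that("hypergeometric tail has the documented boundary and monotonicity behavior", {
  expect_equal(hypergeometric_upper_p(20, 5, 4, 0), 1)
  expect_equal(hypergeometric_upper_p(10, 5, 4, 4), 5 / 210)
  # K = N forces m = n and the tail is the whole distribution
  expect_equal(hypergeometric_upper_p(7, 7, 3, 3), 1)
  expect_error(hypergeometric_upper_p(10, 5, 4, 5), "margins")
  # non-increasing in m at fixed margins
  for (m in 0:3)
    expect_gte(hypergeometric_upper_p(12, 6, 4, m),
               hypergeometric_upper_p(12, 6, 4, m + 1))
})

test_that("pearson_with_p handles exact fits and matches a permutation null", {
  x <- 1:10
  res <- pearson_with_p(x, 2 * x + 1)
  expect_equal(res$r, 1); expect_equal(res$p, 0)
  expect_equal(pearson_with_p(x, -x)$r, -1)
  expect_error(pearson_with_p(x, rep(3, 10)), "constant")
  # permutation oracle at r ~ 0.7, n = 50
  set.seed(3)
  n <- 50
  a <- rnorm(n); b <- 0.7 * a + sqrt(1 - 0.49) * rnorm(n)
  res <- pearson_with_p(a, b)
  perm <- replicate(1e5, abs(cor(a, sample(b))) >= abs(res$r))
  expect_lt(abs(res$p - mean(perm)), 3 * sqrt(res$p / 1e5) + 2e-4)
})

test_that("shared-miRNA counting uses the universe only", {
  edges <- target_edge_table(data.frame(
    mirna_id = c("m1", "m2", "m2", "m3", "m9"),
    target_id = c("L1", "L1", "G1", "G1", "L1")))
  tab <- shared_mirna_table(edges, "L1", "G1", c("m1", "m2", "m3"))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$K, 2)  # m9 outside universe ignored
  expect_equal(tab$n, 2)
  expect_equal(tab$m, 1)
  expect_equal(tab$N, 3)
  expect_equal(tab$shared_mirnas, "m2")
  # disjoint target sets produce no candidate
  e2 <- target_edge_table(data.frame(mirna_id = c("m1", "m2"),
                                     target_id = c("L1", "G1")))
  expect_equal(nrow(shared_mirna_table(e2, "L1", "G1", c("m1", "m2"))), 0)
  # identical sets of size 4: K = n = m = 4
  e3 <- target_edge_table(data.frame(
    mirna_id = rep(paste0("m", 1:4), 2),
    target_id = rep(c("L1", "G1"), each = 4)))
  t3 <- shared_mirna_table(e3, "L1", "G1", paste0("m", 1:4))
  expect_equal(unlist(t3[, c("K", "n", "m", "N")], use.names = FALSE),
               rep(4L, 4))
  expect_error(shared_mirna_table(e3, "L1", "G1", "mX"), "universe")
})

test_that("ceRNA pair filter applies all three strict rules", {
  set.seed(8)
  samples <- sprintf("s%02d", 1:30)
  mk <- function(rows) {
    m <- do.call(rbind, rows)
    colnames(m) <- samples
    m
  }
  z <- rnorm(30)
  lnc <- expression_matrix(mk(list(L1 = z + rnorm(30, 0, 0.3),
                                   L2 = rnorm(30))), "lncRNA", "log2CPM")
  mrna <- expression_matrix(mk(list(G1 = z + rnorm(30, 0, 0.3),
                                    G2 = -z + rnorm(30, 0, 0.3))),
                            "mRNA", "log2CPM")
  edges <- target_edge_table(data.frame(
    mirna_id = c(rep(c("m1", "m2"), 4), paste0("m", 3:10)),
    target_id = c(rep(c("L1", "L2", "G1", "G2"), each = 2),
                  paste0("other", 3:10))))
  pairs <- shared_mirna_table(edges, c("L1", "L2"), c("G1", "G2"),
                              paste0("m", 1:10))
  out <- filter_cerna_pairs(pairs, lnc, mrna, hyper_p_max = 0.05)
  all_p <- attr(out, "all_pairs")
  # L1-G1 positively correlated and enriched -> passes
  expect_true(any(out$lncrna_id == "L1" & out$mrna_id == "G1"))
  # L1-G2 anti-correlated -> rejected despite identical hypergeometric p
  expect_false(any(out$lncrna_id == "L1" & out$mrna_id == "G2"))
  expect_true(all(out$passes))
  expect_true(all(paste(out$lncrna_id, out$mrna_id) %in%
                    paste(all_p$lncrna_id, all_p$mrna_id)))
  # order invariance
  out2 <- filter_cerna_pairs(pairs[rev(seq_len(nrow(pairs))), ], lnc, mrna,
                             hyper_p_max = 0.05)
  expect_setequal(paste(out2$lncrna_id, out2$mrna_id),
                  paste(out$lncrna_id, out$mrna_id))
  expect_error(filter_cerna_pairs(pairs, lnc[1, , drop = FALSE], mrna),
               "L2")
})

test_that("network construction counts nodes and edges deterministically", {
  pairs <- data.frame(lncrna_id = "L1", mrna_id = "G1",
                      shared_mirnas = "m1,m2")
  class(pairs) <- c("cerna_pairs", "data.frame")
  net <- build_cerna_network(pairs, include_mirna_nodes = TRUE)
  expect_equal(nrow(net$nodes), 4)   # L1, G1, m1, m2
  expect_equal(nrow(net$edges), 5)   # 1 pair + 2 miRNAs x 2 partners
  net_off <- build_cerna_network(pairs, include_mirna_nodes = FALSE)
  expect_equal(nrow(net_off$nodes), 2)
  expect_equal(nrow(net_off$edges), 1)
  dup <- rbind(pairs, pairs)
  class(dup) <- c("cerna_pairs", "data.frame")
  expect_equal(nrow(build_cerna_network(dup)$edges), 5)
})

test_that("centralities match hand values and the exhaustive path oracle", {
  # path a-b-c: betweenness (0, 1, 0), degree (1, 2, 1)
  path_net <- build_cerna_network(
    structure(data.frame(lncrna_id = c("a", "b"), mrna_id = c("b", "c"),
                         shared_mirnas = ""),
              class = c("cerna_pairs", "data.frame")),
    include_mirna_nodes = FALSE)
  cent <- centralities(path_net)
  expect_equal(cent$degree[match(c("a", "b", "c"), cent$id)], c(1, 2, 1))
  expect_equal(cent$betweenness[match(c("a", "b", "c"), cent$id)],
               c(0, 1, 0))
  expect_equal(cent$closeness[cent$id == "b"], 2 / 2)
  expect_equal(cent$closeness[cent$id == "a"], 2 / 3)

  # complete graph K4: all betweenness 0
  k4 <- t(utils::combn(letters[1:4], 2))
  k4_net <- build_cerna_network(
    structure(data.frame(lncrna_id = k4[, 1], mrna_id = k4[, 2],
                         shared_mirnas = ""),
              class = c("cerna_pairs", "data.frame")),
    include_mirna_nodes = FALSE)
  expect_true(all(centralities(k4_net)$betweenness == 0))

  # 100 random graphs with <= 8 nodes vs the enumeration oracle
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    a <- random_adjacency(n, runif(1, 0.25, 0.6))
    dimnames(a) <- list(letters[1:n], letters[1:n])
    ee <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
    if (!nrow(ee)) next
    net <- build_cerna_network(
      structure(data.frame(lncrna_id = rownames(a)[ee[, 1]],
                           mrna_id = rownames(a)[ee[, 2]],
                           shared_mirnas = ""),
                class = c("cerna_pairs", "data.frame")),
      include_mirna_nodes = FALSE)
    cent <- centralities(net)
    present <- match(cent$id, rownames(a))
    expect_equal(cent$betweenness,
                 oracle_betweenness(a)[present], tolerance = 1e-10)
  }
})

test_that("network miRNA ranking is truncated, complete and order invariant", {
  pairs <- data.frame(
    lncrna_id = rep("L1", 25), mrna_id = sprintf("G%02d", 1:25),
    shared_mirnas = sprintf("m%02d", 1:25))
  class(pairs) <- c("cerna_pairs", "data.frame")
  net <- build_cerna_network(pairs, include_mirna_nodes = TRUE)
  de <- data.frame(gene_id = sprintf("m%02d", 1:25),
                   log2fc = seq(0.1, 2.5, by = 0.1))
  top <- rank_network_mirnas(net, de, k = 20)
  expect_length(top, 20)
  expect_equal(top[1], "m25")
  expect_length(rank_network_mirnas(net, de[1:5, ], k = 20), 20)
  few <- build_cerna_network(pairs[1:5, ], include_mirna_nodes = TRUE)
  expect_length(rank_network_mirnas(few, de, k = 20), 5)
  net_rev <- build_cerna_network(pairs[rev(1:25), ],
                                 include_mirna_nodes = TRUE)
  expect_equal(rank_network_mirnas(net_rev, de, k = 20), top)
})

test_that("planted ceRNA pairs are recovered with few false positives", {
  for (s in 1:3) {
    run <- default_run(s)
    truth <- run$results$cohort$truth
    planted <- paste(truth$pairs$lncrna_id, truth$pairs$mrna_id)
    passing <- paste(run$results$cerna$passing$lncrna_id,
                     run$results$cerna$passing$mrna_id)
    expect_gte(mean(planted %in% passing), 0.9)
    expect_lte(mean(!passing %in% planted), 0.10)
  }
})
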