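# ceRNA pair inference: shared-miRNA counting against a DE-miRNA
# universe, upper-tail hypergeometric enrichment, tumor co-expression
# filtering, network construction and node centralities.

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `m` shared elements when `n` are
#' drawn from a universe of `N` containing `K` marked elements:
#' `p = sum_{k=m}^{min(K,n)} C(K,k) C(N-K,n-k) / C(N,n)`. Evaluated via
#' the log-space-stable `stats::phyper` upper tail. Vectorized.
#'
#' @param N Universe size.
#' @param K Marked elements (e.g. miRNAs targeting the lncRNA).
#' @param n Draws (e.g. miRNAs targeting the mRNA).
#' @param m Observed overlap.
#' @return p in (0, 1]; `m = 0` gives exactly 1.
#' @export
hypergeometric_upper_p <- function(N, K, n, m) {
  bad <- m < 0 | m > pmin(K, n) | K > N | n > N | N < 0
  if (any(bad))
    stop("invalid hypergeometric margins: need 0 <= m <= min(K, n) <= N")
  stats::phyper(m - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` df; `r = +/-1` returns
#' p = 0. Constant vectors are rejected.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return List with elements `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Pearson correlation undefined")
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) return(list(r = sign(r), p = 0))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Candidate ceRNA pairs from shared miRNA regulators
#'
#' One candidate per (lncRNA, mRNA) combination sharing at least one
#' miRNA from the universe; `K`, `n`, `m`, `N` are computed against the
#' universe only (edges to non-universe miRNAs are ignored).
#'
#' @param targets A [target_edge_table()].
#' @param lnc_ids DE-selected lncRNA ids.
#' @param mrna_ids DE-selected mRNA ids.
#' @param mirna_universe DE-selected miRNAs present in the target table.
#' @return Data.frame of class `cerna_pairs` with columns `lncrna_id`,
#'   `mrna_id`, `K`, `n`, `m`, `N`, `shared_mirnas` (comma-joined) and
#'   unfilled statistics columns.
#' @export
shared_mirna_table <- function(targets, lnc_ids, mrna_ids, mirna_universe) {
  mirna_universe <- intersect(unique(mirna_universe),
                              unique(targets$mirna_id))
  if (!length(mirna_universe)) stop("empty miRNA universe")
  mirna_universe <- sort(mirna_universe)
  ed <- targets[targets$mirna_id %in% mirna_universe, , drop = FALSE]
  inc <- function(ids) {
    mat <- matrix(FALSE, length(ids), length(mirna_universe),
                  dimnames = list(ids, mirna_universe))
    sub <- ed[ed$target_id %in% ids, , drop = FALSE]
    if (nrow(sub)) mat[cbind(sub$target_id, sub$mirna_id)] <- TRUE
    mat
  }
  L <- inc(sort(unique(lnc_ids)))
  R <- inc(sort(unique(mrna_ids)))
  M <- L %*% t(R)                      # shared miRNA counts
  hits <- which(M >= 1, arr.ind = TRUE)
  if (!nrow(hits)) {
    out <- data.frame(lncrna_id = character(), mrna_id = character(),
                      K = integer(), n = integer(), m = integer(),
                      N = integer(), shared_mirnas = character(),
                      hyper_p = numeric(), pcc = numeric(),
                      pcc_p = numeric(), passes = logical())
    class(out) <- c("cerna_pairs", "data.frame")
    return(out)
  }
  Ksum <- rowSums(L); nsum <- rowSums(R)
  shared <- vapply(seq_len(nrow(hits)), function(i)
    paste(mirna_universe[L[hits[i, 1], ] & R[hits[i, 2], ]], collapse = ","),
    "")
  out <- data.frame(
    lncrna_id = rownames(L)[hits[, 1]],
    mrna_id = rownames(R)[hits[, 2]],
    K = as.integer(Ksum[hits[, 1]]),
    n = as.integer(nsum[hits[, 2]]),
    m = as.integer(M[hits]),
    N = length(mirna_universe),
    shared_mirnas = shared,
    hyper_p = NA_real_, pcc = NA_real_, pcc_p = NA_real_,
    passes = NA, stringsAsFactors = FALSE)
  out <- out[order(out$lncrna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cerna_pairs", "data.frame")
  out
}

#' Score and filter ceRNA pairs
#'
#' Fills the hypergeometric p, the tumor-sample Pearson correlation and
#' its p-value for every candidate, and marks pairs passing all three
#' strict conditions: `hyper_p < hyper_p_max`, `pcc > 0` (when
#' required), `pcc_p < pcc_p_max`.
#'
#' @param pairs A `cerna_pairs` table from [shared_mirna_table()].
#' @param expr_lnc,expr_mrna Log-scale [expression_matrix()] objects
#'   covering all pair members.
#' @param sample_ids Samples on which to correlate (typically tumor
#'   samples); default all shared columns.
#' @param hyper_p_max Strict hypergeometric threshold (default 0.05).
#' @param require_positive_pcc Require `pcc > 0` (default `TRUE`).
#' @param pcc_p_max Strict correlation p threshold (default 0.05);
#'   `NULL` disables the significance filter.
#' @return The scored table restricted to passing pairs, with the full
#'   scored table in attribute `"all_pairs"`.
#' @export
filter_cerna_pairs <- function(pairs, expr_lnc, expr_mrna,
                               sample_ids = NULL,
                               hyper_p_max = 0.05,
                               require_positive_pcc = TRUE,
                               pcc_p_max = 0.05) {
  stopifnot(inherits(pairs, "cerna_pairs"))
  if (!nrow(pairs)) {
    attr(pairs, "all_pairs") <- pairs
    return(pairs)
  }
  xl <- unclass_mat(expr_lnc); xm <- unclass_mat(expr_mrna)
  if (is.null(sample_ids))
    sample_ids <- intersect(colnames(xl), colnames(xm))
  miss_l <- setdiff(unique(pairs$lncrna_id), rownames(xl))
  miss_m <- setdiff(unique(pairs$mrna_id), rownames(xm))
  if (length(miss_l) || length(miss_m))
    stop("pair member(s) missing from expression: ",
         paste(c(miss_l, miss_m), collapse = ", "))
  if (length(sample_ids) < 3) stop("need >= 3 samples for correlation")
  xl <- xl[, sample_ids, drop = FALSE]; xm <- xm[, sample_ids, drop = FALSE]
  lu <- unique(pairs$lncrna_id); mu <- unique(pairs$mrna_id)
  cors <- stats::cor(t(xl[lu, , drop = FALSE]), t(xm[mu, , drop = FALSE]))
  ns <- length(sample_ids)
  pairs$hyper_p <- hypergeometric_upper_p(pairs$N, pairs$K, pairs$n, pairs$m)
  r <- cors[cbind(match(pairs$lncrna_id, lu), match(pairs$mrna_id, mu))]
  r2 <- pmin(r^2, 1 - 1e-15)
  tt <- r * sqrt((ns - 2) / (1 - r2))
  pairs$pcc <- r
  pairs$pcc_p <- ifelse(abs(r) >= 1 - 1e-15, 0,
                        2 * stats::pt(-abs(tt), df = ns - 2))
  ok <- pairs$hyper_p < hyper_p_max
  if (require_positive_pcc) ok <- ok & pairs$pcc > 0
  if (!is.null(pcc_p_max)) ok <- ok & pairs$pcc_p < pcc_p_max
  pairs$passes <- ok
  passing <- pairs[ok, , drop = FALSE]
  rownames(passing) <- NULL
  attr(passing, "all_pairs") <- pairs
  class(passing) <- c("cerna_pairs", "data.frame")
  passing
}

#' Build the ceRNA network from passing pairs
#'
#' Nodes are the pair lncRNAs and mRNAs (plus, optionally, the shared
#' miRNAs with `"targets"` edges to both partners); pair edges carry the
#' `"cerna"` interaction label. Node and edge ordering is deterministic.
#'
#' @param passing_pairs A `cerna_pairs` table of passing pairs.
#' @param include_mirna_nodes Add shared miRNAs as nodes (default
#'   `TRUE`).
#' @return List of class `cerna_network` with data.frames `nodes`
#'   (`id`, `type`) and `edges` (`source`, `interaction`, `target`), and
#'   the pair table in `$pairs`.
#' @export
build_cerna_network <- function(passing_pairs, include_mirna_nodes = TRUE) {
  pr <- unique(as.data.frame(passing_pairs)[, c("lncrna_id", "mrna_id",
                                                "shared_mirnas")])
  edges <- data.frame(source = pr$lncrna_id,
                      interaction = rep("cerna", nrow(pr)),
                      target = pr$mrna_id, stringsAsFactors = FALSE)
  nodes <- rbind(
    data.frame(id = unique(pr$lncrna_id),
               type = rep("lncRNA", length(unique(pr$lncrna_id)))),
    data.frame(id = unique(pr$mrna_id),
               type = rep("mRNA", length(unique(pr$mrna_id)))))
  if (include_mirna_nodes && nrow(pr)) {
    mir_edges <- do.call(rbind, lapply(seq_len(nrow(pr)), function(i) {
      mirs <- strsplit(pr$shared_mirnas[i], ",", fixed = TRUE)[[1]]
      mirs <- mirs[nzchar(mirs)]
      if (!length(mirs)) return(NULL)
      data.frame(source = rep(mirs, 2), interaction = "targets",
                 target = rep(c(pr$lncrna_id[i], pr$mrna_id[i]),
                              each = length(mirs)),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(mir_edges)) {
      mir_edges <- unique(mir_edges)
      edges <- rbind(edges, mir_edges)
      mir_ids <- unique(mir_edges$source)
      nodes <- rbind(nodes, data.frame(id = mir_ids,
                                       type = rep("miRNA",
                                                  length(mir_ids))))
    }
  }
  # a node id doubling as lncRNA and mRNA keeps its first (lncRNA) type
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  edges <- unique(edges)
  edges <- edges[order(edges$source, edges$interaction, edges$target), ]
  nodes <- nodes[order(nodes$type, nodes$id), ]
  rownames(edges) <- rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 pairs = as.data.frame(passing_pairs)),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("cerna_network: %d node(s) [%s], %d edge(s)\n",
              nrow(x$nodes),
              paste(names(table(x$nodes$type)),
                    table(x$nodes$type), sep = ":", collapse = " "),
              nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(network, interactions = NULL) {
  edges <- network$edges
  if (!is.null(interactions))
    edges <- edges[edges$interaction %in% interactions, , drop = FALSE]
  ids <- if (is.null(interactions)) network$nodes$id
         else sort(unique(c(edges$source, edges$target)))
  igraph::graph_from_data_frame(edges[, c("source", "target")],
                                directed = FALSE,
                                vertices = data.frame(name = ids))
}

#' Degree, betweenness and closeness for every network node
#'
#' Undirected, unweighted: degree is the edge count at the node;
#' betweenness is the Brandes shortest-path count (unnormalized);
#' closeness for a node is `(reachable - 1) / sum of distances` within
#' its component, 0 for isolated nodes.
#'
#' @param network A `cerna_network`.
#' @return Data.frame with columns `id`, `type`, `degree`,
#'   `betweenness`, `closeness`.
#' @export
centralities <- function(network) {
  if (!nrow(network$nodes)) stop("network has no nodes")
  g <- as_igraph(network)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  d <- igraph::distances(g)
  clo <- apply(d, 1, function(row) {
    reach <- sum(is.finite(row)) - 1
    if (reach <= 0) return(0)
    reach / sum(row[is.finite(row) & row > 0])
  })
  out <- data.frame(id = igraph::V(g)$name,
                    degree = as.numeric(deg),
                    betweenness = as.numeric(btw),
                    closeness = as.numeric(clo),
                    stringsAsFactors = FALSE)
  out <- merge(network$nodes, out, by = "id", sort = TRUE)
  out[order(out$id), ]
}

#' Rank the miRNAs participating in passing ceRNA pairs
#'
#' miRNAs shared by at least one passing pair, ranked by `|log2fc|`
#' descending (ties lexicographic), truncated to `k`.
#'
#' @param network A `cerna_network` built with miRNA nodes.
#' @param de miRNA `de_result`.
#' @param k Maximum number returned (default 20).
#' @return Character vector of miRNA ids in rank order.
#' @export
rank_network_mirnas <- function(network, de, k = 20) {
  mirs <- network$nodes$id[network$nodes$type == "miRNA"]
  if (!length(mirs)) return(character())
  lfc <- abs(de$log2fc[match(mirs, de$gene_id)])
  lfc[is.na(lfc)] <- 0
  ord <- order(-lfc, mirs)
  mirs[ord][seq_len(min(k, length(mirs)))]
}
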