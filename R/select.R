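# Candidate nomination: intersect high-degree ceRNA lncRNAs, the
# TNM-associated modules and the strong co-expression network.

#' Build the lncRNA co-expression network at a PCC cutoff
#'
#' All lncRNA-lncRNA and lncRNA-mRNA pairs with Pearson correlation at
#' or above `pcc_min` (inclusive), computed across the supplied samples.
#' Edges are stored once with deterministic ordering and `type` tags.
#'
#' @param expr_lnc lncRNA [expression_matrix()] (log scale).
#' @param expr_mrna mRNA [expression_matrix()] (log scale).
#' @param pcc_min Inclusive correlation cutoff (default 0.7).
#' @param sample_ids Samples to correlate over (default: the shared
#'   columns; matrices must agree on them).
#' @return Data.frame of class `coexpression_network` with columns
#'   `gene_a`, `gene_b`, `pcc`, `type` (`"lnc-lnc"` or `"lnc-mrna"`).
#' @export
build_coexpression_network <- function(expr_lnc, expr_mrna, pcc_min = 0.7,
                                       sample_ids = NULL) {
  xl <- unclass_mat(expr_lnc); xm <- unclass_mat(expr_mrna)
  if (is.null(sample_ids)) {
    if (!identical(sort(colnames(xl)), sort(colnames(xm))))
      stop("sample ids differ between matrices; supply sample_ids")
    sample_ids <- colnames(xl)
  }
  miss <- setdiff(sample_ids, intersect(colnames(xl), colnames(xm)))
  if (length(miss)) stop("sample(s) absent from a matrix: ",
                         paste(miss, collapse = ", "))
  xl <- xl[, sample_ids, drop = FALSE]; xm <- xm[, sample_ids, drop = FALSE]
  keep_var <- function(x) x[apply(x, 1, stats::sd) > 0, , drop = FALSE]
  xl <- keep_var(xl); xm <- keep_var(xm)
  ll <- stats::cor(t(xl))
  lm_ <- stats::cor(t(xl), t(xm))
  up <- which(upper.tri(ll) & ll >= pcc_min, arr.ind = TRUE)
  e1 <- data.frame(gene_a = rownames(ll)[up[, 1]],
                   gene_b = rownames(ll)[up[, 2]],
                   pcc = ll[up], type = "lnc-lnc",
                   stringsAsFactors = FALSE)
  hit <- which(lm_ >= pcc_min, arr.ind = TRUE)
  e2 <- data.frame(gene_a = rownames(lm_)[hit[, 1]],
                   gene_b = colnames(lm_)[hit[, 2]],
                   pcc = lm_[hit], type = "lnc-mrna",
                   stringsAsFactors = FALSE)
  out <- rbind(e1, e2)
  swap <- out$type == "lnc-lnc" & out$gene_a > out$gene_b
  tmp <- out$gene_a[swap]; out$gene_a[swap] <- out$gene_b[swap]
  out$gene_b[swap] <- tmp
  out <- out[order(out$type, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coexpression_network", "data.frame")
  out
}

#' Top-degree lncRNA nodes of the ceRNA pair graph
#'
#' Degree is computed on the lncRNA-mRNA pair edges only (miRNA nodes
#' excluded). At least `ceiling(fraction x count)` nodes are returned;
#' all nodes tied with the boundary degree are included.
#'
#' @param network A `cerna_network`.
#' @param fraction Top fraction (default 0.20).
#' @param node_type Node type ranked (default `"lncRNA"`).
#' @return Character vector of node ids (sorted).
#' @export
top_degree_nodes <- function(network, fraction = 0.20,
                             node_type = "lncRNA") {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  pe <- network$edges[network$edges$interaction == "cerna", , drop = FALSE]
  ids <- network$nodes$id[network$nodes$type == node_type]
  if (!length(ids) || !nrow(pe)) return(character())
  deg <- table(factor(c(pe$source, pe$target), levels = ids))
  deg <- sort(deg, decreasing = TRUE)
  k <- ceiling(fraction * length(deg))
  boundary <- as.integer(deg[k])
  sort(names(deg)[as.integer(deg) >= boundary])
}

#' Nominate candidate lncRNAs by triple intersection
#'
#' A candidate lncRNA must (i) be a top-degree node of the ceRNA pair
#' graph, (ii) belong to a TNM-significant module, and (iii) have at
#' least one co-expression edge at the PCC cutoff. Its linked mRNA set
#' is the union of its ceRNA partners and its lncRNA-mRNA co-expression
#' partners, tagged by evidence.
#'
#' @param cerna A `cerna_network`.
#' @param modules A `module_set` (for the gene-to-module assignment).
#' @param sig_modules Output of [significant_modules()] (or a character
#'   vector of module ids).
#' @param coexp A `coexpression_network`.
#' @param fraction Top-degree fraction (default 0.20).
#' @return List of class `candidate_report`: data.frame `candidates`
#'   (id, ceRNA degree, module, module best p, partner counts) and
#'   data.frame `targets` (lncrna_id, mrna_id, evidence).
#' @export
select_candidates <- function(cerna, modules, sig_modules, coexp,
                              fraction = 0.20) {
  sig_ids <- if (is.data.frame(sig_modules)) sig_modules$module
             else as.character(sig_modules)
  sig_p <- if (is.data.frame(sig_modules) && nrow(sig_modules))
    stats::setNames(sig_modules$best_p, sig_modules$module)
  else stats::setNames(numeric(), character())
  empty <- function() {
    structure(list(
      candidates = data.frame(lncrna_id = character(), degree = numeric(),
                              module = character(), module_best_p = numeric(),
                              n_cerna_mrna = integer(), n_coexp_mrna = integer(),
                              stringsAsFactors = FALSE),
      targets = data.frame(lncrna_id = character(), mrna_id = character(),
                           evidence = character(), stringsAsFactors = FALSE)),
      class = "candidate_report")
  }
  if (!length(sig_ids)) {
    warning("no TNM-significant modules: empty candidate report")
    return(empty())
  }
  hubs <- top_degree_nodes(cerna, fraction, "lncRNA")
  assignment <- modules$assignment
  in_sig <- hubs[assignment[hubs] %in% sig_ids & !is.na(assignment[hubs])]
  has_edge <- unique(c(coexp$gene_a, coexp$gene_b))
  cands <- sort(intersect(in_sig, has_edge))
  if (!length(cands)) return(empty())

  pe <- cerna$edges[cerna$edges$interaction == "cerna", , drop = FALSE]
  deg <- table(factor(c(pe$source, pe$target),
                      levels = cerna$nodes$id[cerna$nodes$type == "lncRNA"]))
  tgt <- do.call(rbind, lapply(cands, function(g) {
    ce <- sort(unique(c(pe$target[pe$source == g], pe$source[pe$target == g])))
    cx <- coexp[coexp$type == "lnc-mrna" &
                  (coexp$gene_a == g | coexp$gene_b == g), , drop = FALSE]
    cxp <- sort(unique(ifelse(cx$gene_a == g, cx$gene_b, cx$gene_a)))
    all_m <- sort(union(ce, cxp))
    if (!length(all_m)) return(NULL)
    data.frame(lncrna_id = g, mrna_id = all_m,
               evidence = ifelse(all_m %in% ce & all_m %in% cxp, "both",
                                 ifelse(all_m %in% ce, "cerna", "coexp")),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tgt))
    tgt <- data.frame(lncrna_id = character(), mrna_id = character(),
                      evidence = character(), stringsAsFactors = FALSE)
  cand_df <- data.frame(
    lncrna_id = cands,
    degree = as.numeric(deg[cands]),
    module = unname(assignment[cands]),
    module_best_p = unname(sig_p[assignment[cands]]),
    n_cerna_mrna = vapply(cands, function(g)
      sum(tgt$lncrna_id == g & tgt$evidence != "coexp"), 0L),
    n_coexp_mrna = vapply(cands, function(g)
      sum(tgt$lncrna_id == g & tgt$evidence != "cerna"), 0L),
    stringsAsFactors = FALSE)
  rownames(cand_df) <- NULL
  structure(list(candidates = cand_df, targets = tgt),
            class = "candidate_report")
}

#' Candidate-to-target-mRNA table
#'
#' One row per (candidate lncRNA, linked mRNA) with the evidence label
#' (`cerna`, `coexp` or `both`), deterministically ordered; the distinct
#' mRNA count is attached as attribute `"n_distinct_mrna"`.
#'
#' @param report A `candidate_report`.
#' @return Data.frame with columns `lncrna_id`, `mrna_id`, `evidence`.
#' @export
candidate_target_table <- function(report) {
  stopifnot(inherits(report, "candidate_report"))
  tgt <- report$targets
  tgt <- tgt[order(tgt$lncrna_id, tgt$mrna_id), , drop = FALSE]
  rownames(tgt) <- NULL
  attr(tgt, "n_distinct_mrna") <- length(unique(tgt$mrna_id))
  tgt
}
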