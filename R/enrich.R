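# Generic over-representation analysis against GMT gene-set
# collections: a local stand-in for the usual hosted annotation tools.

#' Hypergeometric over-representation analysis
#'
#' Each set is intersected with the universe before testing; the
#' upper-tail hypergeometric p uses `N = |universe|`,
#' `K = |set ∩ universe|`, `n = |query|`, `m = |overlap|`. BH FDR is
#' applied once across all tested sets; rows are sorted by p then set
#' name.
#'
#' @param query Gene id set; must be contained in `universe`.
#' @param sets A [gene_set_collection()].
#' @param universe Universe gene ids (for expression studies, usually
#'   all genes in the matrix, not the whole genome).
#' @return Data.frame with columns `set_name`, `k_overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `fdr`, `overlap_genes`
#'   (comma-joined).
#' @export
ora <- function(query, sets, universe) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  out_of_universe <- setdiff(query, universe)
  if (length(out_of_universe))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(out_of_universe, 10), collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set_u <- intersect(sets[[nm]], universe)
    ov <- intersect(set_u, query)
    K <- length(set_u); m <- length(ov)
    data.frame(set_name = nm, k_overlap = m, set_size = K,
               query_size = n, universe_size = N,
               p = if (K == 0) 1 else hypergeometric_upper_p(N, K, n, m),
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- benjamini_hochberg(res$p)
  res <- res[order(res$p, res$set_name),
             c("set_name", "k_overlap", "set_size", "query_size",
               "universe_size", "p", "fdr", "overlap_genes")]
  rownames(res) <- NULL
  res
}
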