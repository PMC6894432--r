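# Differential-expression screening stage: TMM normalization, log2-CPM
# transform, a paired per-gene t-test on per-pair log2 differences, BH
# FDR, and the two selection rules (FDR/log2FC thresholds for mRNA and
# lncRNA; top/bottom-k fold change for miRNA).

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Per-sample scaling factors computed against a reference sample: M
#' (log-ratio) and A (log-abundance) values on genes expressed in both
#' libraries, with 30% of the M extremes and 5% of the A extremes trimmed
#' from each tail, a precision-weighted mean M, and a final rescaling so
#' the factors have geometric mean 1.
#'
#' @param counts An [expression_matrix()] with unit `"counts"`.
#' @param ref_sample Optional reference sample id; by default the sample
#'   whose upper-quartile count fraction is closest to the mean.
#' @return Object of class `norm_factors`: named numeric vector of
#'   factors with a `method` attribute.
#' @export
tmm_factors <- function(counts, ref_sample = NULL) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (expr_unit(counts) != "counts")
    stop("tmm_factors requires unit 'counts', got '", expr_unit(counts), "'")
  x <- unclass_mat(counts)
  lib <- colSums(x)
  if (any(lib == 0))
    stop("all-zero sample(s): ",
         paste(colnames(x)[lib == 0], collapse = ", "))
  if (is.null(ref_sample)) {
    uq <- apply(x, 2, function(v) stats::quantile(v, 0.75)) / lib
    ref_sample <- colnames(x)[which.min(abs(uq - mean(uq)))]
  } else if (!ref_sample %in% colnames(x))
    stop("ref_sample '", ref_sample, "' not in matrix")
  ref <- x[, ref_sample] / lib[ref_sample]
  f <- vapply(colnames(x), function(s) {
    obs <- x[, s] / lib[s]
    keep <- obs > 0 & ref > 0
    if (!any(keep)) return(1)
    m <- log2(obs[keep] / ref[keep])
    a <- 0.5 * log2(obs[keep] * ref[keep])
    # asymptotic (delta-method) precision weights as in the standard TMM
    w <- (1 - x[keep, s] / lib[s]) / x[keep, s] +
      (1 - x[keep, ref_sample] / lib[ref_sample]) / x[keep, ref_sample]
    if (max(abs(m)) < 1e-6) return(1)
    lM <- stats::quantile(m, 0.30); hM <- stats::quantile(m, 0.70)
    lA <- stats::quantile(a, 0.05); hA <- stats::quantile(a, 0.95)
    use <- m >= lM & m <= hM & a >= lA & a <= hA
    if (!any(use)) return(1)
    2^(sum(m[use] / w[use]) / sum(1 / w[use]))
  }, 0)
  f <- f / exp(mean(log(f)))
  structure(f, method = "TMM", class = "norm_factors")
}

#' Convert counts to log2 counts-per-million
#'
#' `log2((count + prior) / (library size x factor) x 1e6)`.
#'
#' @param counts An [expression_matrix()] with unit `"counts"`.
#' @param factors Optional [tmm_factors()] result (defaults to 1 for all
#'   samples).
#' @param prior Positive pseudo-count added before the log (default 0.5).
#' @return An [expression_matrix()] with unit `"log2CPM"`.
#' @export
to_log2cpm <- function(counts, factors = NULL, prior = 0.5) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (expr_unit(counts) != "counts")
    stop("to_log2cpm requires unit 'counts'")
  if (prior <= 0) stop("prior must be > 0")
  x <- unclass_mat(counts)
  if (is.null(factors)) factors <- stats::setNames(rep(1, ncol(x)), colnames(x))
  if (!all(colnames(x) %in% names(factors)))
    stop("factors missing for sample(s): ",
         paste(setdiff(colnames(x), names(factors)), collapse = ", "))
  eff <- colSums(x) * as.numeric(factors[colnames(x)])
  vals <- log2(sweep(x + prior, 2, eff, "/") * 1e6)
  expression_matrix(vals, role = expr_role(counts), unit = "log2CPM")
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Input validation plus the standard BH step-up transform
#' (`stats::p.adjust(method = "BH")`).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in \[0, 1\], same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Paired per-gene differential test on log2 expression
#'
#' For each gene, a two-sided paired t-test on the per-pair (tumor minus
#' normal) log2 differences: `log2fc` is the mean per-pair difference,
#' the p-value comes from a t distribution on `n_pairs - 1` degrees of
#' freedom, and FDR is BH across all genes in the matrix. Genes with
#' zero variance across pairs get p = 1 with a warning. An `unpaired`
#' variant (Welch test on tumor vs normal groups) is available behind a
#' flag.
#'
#' @param log_expr An [expression_matrix()] on a log2 unit.
#' @param clinical A [clinical_table()]; every sample column must belong
#'   to a complete tumor/normal pair (>= 3 pairs).
#' @param paired If `FALSE`, use an unpaired Welch test instead.
#' @return Data.frame of class `de_result` with columns `gene_id`,
#'   `log2fc`, `p_value`, `fdr`, `mean_log2_expr`.
#' @export
paired_de_test <- function(log_expr, clinical, paired = TRUE) {
  stopifnot(inherits(log_expr, "expr_matrix"),
            inherits(clinical, "clinical_table"))
  if (!expr_unit(log_expr) %in% .LOG_UNITS)
    stop("paired_de_test requires a log2 unit matrix")
  x <- unclass_mat(log_expr)
  cl <- clinical[match(colnames(x), clinical$sample_id), ]
  if (any(is.na(cl$sample_id)))
    stop("sample(s) missing from clinical table: ",
         paste(setdiff(colnames(x), clinical$sample_id), collapse = ", "))
  if (paired) {
    if (any(is.na(cl$pair_id)))
      stop("unpaired sample(s) present: ",
           paste(cl$sample_id[is.na(cl$pair_id)], collapse = ", "))
    pairs <- unique(cl$pair_id)
    ts <- cl$sample_id[match(paste0(pairs, ".tumor"),
                             paste0(cl$pair_id, ".", cl$condition))]
    ns <- cl$sample_id[match(paste0(pairs, ".normal"),
                             paste0(cl$pair_id, ".", cl$condition))]
    if (any(is.na(ts)) || any(is.na(ns)))
      stop("incomplete tumor/normal pair(s): ",
           paste(pairs[is.na(ts) | is.na(ns)], collapse = ", "))
    n <- length(pairs)
    if (n < 3) stop("need >= 3 complete pairs, got ", n)
    d <- x[, ts, drop = FALSE] - x[, ns, drop = FALSE]
    lfc <- rowMeans(d)
    sdd <- apply(d, 1, stats::sd)
    tt <- lfc / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(tt), df = n - 1)
    zv <- sdd == 0
    if (any(zv)) {
      warning(sum(zv), " zero-variance gene(s) set to p = 1")
      p[zv] <- 1
    }
  } else {
    ti <- cl$condition == "tumor"; ni <- cl$condition == "normal"
    if (sum(ti) < 2 || sum(ni) < 2) stop("need >= 2 samples per group")
    mt <- rowMeans(x[, ti, drop = FALSE]); mn <- rowMeans(x[, ni, drop = FALSE])
    vt <- apply(x[, ti, drop = FALSE], 1, stats::var)
    vn <- apply(x[, ni, drop = FALSE], 1, stats::var)
    lfc <- mt - mn
    se2 <- vt / sum(ti) + vn / sum(ni)
    df <- se2^2 / ((vt / sum(ti))^2 / (sum(ti) - 1) +
                   (vn / sum(ni))^2 / (sum(ni) - 1))
    tt <- lfc / sqrt(se2)
    p <- 2 * stats::pt(-abs(tt), df = df)
    zv <- se2 == 0
    if (any(zv)) {
      warning(sum(zv), " zero-variance gene(s) set to p = 1")
      p[zv] <- 1
    }
  }
  res <- data.frame(gene_id = rownames(x), log2fc = lfc, p_value = p,
                    fdr = benjamini_hochberg(p),
                    mean_log2_expr = rowMeans(x),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Select differentially expressed genes by FDR and fold-change
#'
#' Strict thresholds, after the printed rules `FDR < 0.01` and
#' `|logFC| > 1`.
#'
#' @param de A `de_result` from [paired_de_test()].
#' @param fdr_max FDR threshold (strict `<`), default 0.01.
#' @param min_abs_log2fc Fold-change threshold (strict `>`), default 1.
#' @return Character vector of selected gene ids (sorted).
#' @export
select_de_genes <- function(de, fdr_max = 0.01, min_abs_log2fc = 1) {
  if (fdr_max <= 0 || min_abs_log2fc <= 0)
    stop("thresholds must be positive")
  sort(de$gene_id[de$fdr < fdr_max & abs(de$log2fc) > min_abs_log2fc])
}

#' Select the k most up- and k most down-regulated miRNAs
#'
#' Union of the k largest and k smallest log2 fold changes; ties at the
#' boundary broken by lexicographic gene id, so the result always has
#' exactly `2 * k` members.
#'
#' @param de A `de_result` for the miRNA matrix.
#' @param k Count per tail (default 10).
#' @return Character vector of `2k` miRNA ids (sorted).
#' @export
select_top_bottom_mirnas <- function(de, k = 10) {
  if (nrow(de) < 2 * k)
    stop("need >= ", 2 * k, " miRNAs, got ", nrow(de))
  ord_hi <- order(-de$log2fc, de$gene_id)
  top <- de$gene_id[ord_hi[seq_len(k)]]
  rest <- de[!de$gene_id %in% top, , drop = FALSE]
  ord_lo <- order(rest$log2fc, rest$gene_id)
  bottom <- rest$gene_id[ord_lo[seq_len(k)]]
  sort(c(top, bottom))
}
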