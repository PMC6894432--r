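# Signed weighted co-expression core: soft-threshold selection by
# scale-free fit, signed adjacency, topological overlap, average-linkage
# module detection with static cut and eigengene merging, eigengene
# extraction and module-trait correlation.

#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta`; the diagonal is set to 0 so that
#' connectivity sums exclude self-adjacency.
#'
#' @param cor_matrix Symmetric correlation matrix with unit diagonal.
#' @param beta Positive soft-threshold exponent.
#' @return Symmetric adjacency matrix in \[0, 1\] with zero diagonal.
#' @export
signed_adjacency <- function(cor_matrix, beta) {
  if (beta <= 0) stop("beta must be > 0")
  if (!isSymmetric(unname(cor_matrix), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  if (any(cor_matrix < -1 - 1e-8 | cor_matrix > 1 + 1e-8))
    stop("correlation entries must lie in [-1, 1]")
  a <- ((1 + pmin(pmax(cor_matrix, -1), 1)) / 2)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix (TOM) similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, `TOM_ii = 1`; dissimilarity is `1 - TOM`.
#'
#' @param adjacency Symmetric matrix, entries in \[0, 1\], zero
#'   diagonal.
#' @return TOM similarity matrix.
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be 0")
  if (any(adjacency < 0 | adjacency > 1))
    stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(adjacency)
  shared <- adjacency %*% adjacency
  mink <- outer(k, k, pmin)
  tom <- (shared + adjacency) / (mink + 1 - adjacency)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the signed adjacency is built, per-gene
#' connectivity `k_i` is binned on log10 scale, and log10(frequency) is
#' regressed on log10(mean k) per bin. The fit index is
#' `-sign(slope) * R^2` (positive when the degree distribution decays as
#' a power law). The chosen power is the smallest candidate whose index
#' reaches `r2_min`, else the argmax with a warning.
#'
#' @param expr Log-scale [expression_matrix()] (or plain matrix),
#'   genes x samples.
#' @param powers Candidate integer powers.
#' @param r2_min Required fit index (default 0.85).
#' @param n_bins Connectivity histogram bins (default 10).
#' @return List of class `soft_threshold_scan`: data.frame `scan`
#'   (`power`, `fit_r2`, `mean_connectivity`) and `chosen_power`.
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, 12, 14, 16),
                                r2_min = 0.85, n_bins = 10) {
  x <- if (inherits(expr, "expr_matrix")) unclass_mat(expr) else expr
  if (ncol(x) < 2) stop("need >= 2 samples")
  if (any(powers <= 0)) stop("powers must be positive")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene row(s): ",
         paste(rownames(x)[sds == 0], collapse = ", "))
  cors <- stats::cor(t(x))
  scan <- data.frame(power = powers, fit_r2 = NA_real_,
                     mean_connectivity = NA_real_)
  for (i in seq_along(powers)) {
    a <- signed_adjacency(cors, powers[i])
    k <- rowSums(a)
    scan$mean_connectivity[i] <- mean(k)
    scan$fit_r2[i] <- scale_free_fit(k, n_bins)
  }
  qual <- which(scan$fit_r2 >= r2_min)
  if (length(qual)) chosen <- powers[min(qual)]
  else {
    chosen <- powers[which.max(scan$fit_r2)]
    warning("no candidate power reached r2_min = ", r2_min,
            "; using argmax power ", chosen)
  }
  structure(list(scan = scan, chosen_power = chosen, r2_min = r2_min),
            class = "soft_threshold_scan")
}

# Scale-free topology fit index for a connectivity vector: bin log10(k),
# regress log10(freq) on log10(mean k); returns -sign(slope) * R^2.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  cuts <- cut(k, breaks = n_bins)
  freq <- tapply(k, cuts, length)
  meank <- tapply(k, cuts, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(NA_real_)
  lx <- log10(meank[keep]); ly <- log10(freq[keep] / sum(freq[keep]))
  fit <- stats::lm(ly ~ lx)
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Module eigengene: first principal component of a module
#'
#' Member genes are standardized across samples; the eigengene is the
#' first principal-component score vector over samples, scaled to unit
#' variance, with its sign chosen so that correlation with the module's
#' mean standardized expression is positive.
#'
#' @param expr Log-scale [expression_matrix()] or matrix
#'   (genes x samples).
#' @param member_gene_ids At least 2 member gene ids.
#' @return Named numeric vector (per sample).
#' @export
module_eigengene <- function(expr, member_gene_ids) {
  x <- if (inherits(expr, "expr_matrix")) unclass_mat(expr) else expr
  if (length(member_gene_ids) < 2)
    stop("need >= 2 member genes, got ", length(member_gene_ids))
  if (ncol(x) < 3) stop("need >= 3 samples")
  miss <- setdiff(member_gene_ids, rownames(x))
  if (length(miss)) stop("member gene(s) missing from expression: ",
                         paste(miss, collapse = ", "))
  z <- t(scale(t(x[member_gene_ids, , drop = FALSE])))
  z[!is.finite(z)] <- 0
  sv <- svd(z, nu = 0, nv = 1)
  eig <- sv$v[, 1]
  s <- stats::sd(eig)
  if (s > 0) eig <- eig / s
  avg <- colMeans(z)
  if (stats::sd(avg) > 0 && stats::cor(eig, avg) < 0) eig <- -eig
  stats::setNames(eig, colnames(x))
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering with a static cut at
#' `cut_height`; clusters smaller than `min_module_size` become
#' `"unassigned"`; modules whose eigengenes are closer than
#' `merge_diss_max` (dissimilarity `1 - cor`) are merged iteratively
#' until stable. Labels are deterministic: `M1, M2, ...` by decreasing
#' size, ties broken by the lexicographically smallest member id.
#'
#' @param dissimilarity Square matrix in \[0, 1\] (`1 - TOM`), with
#'   gene ids as dimnames.
#' @param min_module_size Minimum module size (default 30).
#' @param cut_height Static tree-cut height (default 0.985).
#' @param merge_diss_max Eigengene-dissimilarity merge threshold
#'   (default 0.25).
#' @param expr Expression matrix for the eigengene merge and membership
#'   pruning steps; if `NULL`, both are skipped with a warning.
#' @param kme_min Minimum module membership (correlation of a gene with
#'   its module eigengene); assigned genes below it are returned to
#'   `"unassigned"` (default 0.3, the conventional kME floor). Guards
#'   against background genes absorbed by the static cut.
#' @return List of class `module_set`: named character vector
#'   `assignment`, integer table `sizes`, `merge_heights` from the
#'   dendrogram, and (when computed) the eigengene matrix `eigengenes`
#'   (module x sample).
#' @export
detect_modules <- function(dissimilarity, min_module_size = 30,
                           cut_height = 0.985, merge_diss_max = 0.25,
                           expr = NULL, kme_min = 0.3) {
  d <- as.matrix(dissimilarity)
  if (nrow(d) != ncol(d)) stop("dissimilarity must be square")
  ids <- rownames(d)
  if (is.null(ids)) ids <- colnames(d)
  if (is.null(ids)) stop("dissimilarity needs gene ids as dimnames")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  names(cl) <- ids
  assignment <- relabel_modules(cl, min_module_size)
  if (!is.null(expr)) {
    assignment <- merge_close_modules(assignment, expr, merge_diss_max,
                                      min_module_size)
    assignment <- prune_by_kme(assignment, expr, kme_min, min_module_size)
  } else if (any(assignment != "unassigned")) {
    warning("no expression supplied: eigengene merge and kME pruning skipped")
  }
  mods <- setdiff(unique(assignment), "unassigned")
  eigengenes <- NULL
  if (!is.null(expr) && length(mods)) {
    x <- if (inherits(expr, "expr_matrix")) unclass_mat(expr) else expr
    eigengenes <- t(vapply(mods, function(mm)
      module_eigengene(x, names(assignment)[assignment == mm]),
      numeric(ncol(x))))
    rownames(eigengenes) <- mods
  }
  structure(list(assignment = assignment,
                 sizes = table(assignment),
                 merge_heights = hc$height,
                 eigengenes = eigengenes),
            class = "module_set")
}

# Deterministic module labels: size-descending, ties by smallest member
# id; clusters under min_size become "unassigned".
relabel_modules <- function(cl, min_size) {
  tab <- table(cl)
  keep <- names(tab)[tab >= min_size]
  first_member <- vapply(keep, function(g) min(names(cl)[cl == g]), "")
  ord <- order(-as.integer(tab[keep]), first_member)
  lab <- stats::setNames(rep("unassigned", length(cl)), names(cl))
  for (i in seq_along(ord))
    lab[cl == as.integer(keep[ord[i]])] <- sprintf("M%d", i)
  lab
}

# Iteratively merge modules whose eigengene dissimilarity (1 - cor) is
# below merge_diss_max, then relabel deterministically.
merge_close_modules <- function(assignment, expr, merge_diss_max,
                                min_size) {
  x <- if (inherits(expr, "expr_matrix")) unclass_mat(expr) else expr
  repeat {
    mods <- setdiff(unique(assignment), "unassigned")
    if (length(mods) < 2) break
    eig <- vapply(mods, function(mm)
      module_eigengene(x, names(assignment)[assignment == mm]),
      numeric(ncol(x)))
    dd <- 1 - stats::cor(eig)
    diag(dd) <- Inf
    if (min(dd) >= merge_diss_max) break
    idx <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    a <- mods[idx[1]]; b <- mods[idx[2]]
    assignment[assignment == b] <- a
  }
  # re-derive deterministic labels from the merged grouping
  grp <- match(assignment, unique(assignment[assignment != "unassigned"]))
  grp[is.na(grp)] <- 0
  cl <- stats::setNames(grp + 1L, names(assignment))  # 1 = unassigned bucket
  lab <- relabel_modules(cl[cl > 1L], min_size)
  out <- stats::setNames(rep("unassigned", length(assignment)),
                         names(assignment))
  out[names(lab)] <- lab
  out
}

# Return weak members (cor with own module eigengene < kme_min) to
# "unassigned", then relabel deterministically; modules falling under
# min_size dissolve.
prune_by_kme <- function(assignment, expr, kme_min, min_size) {
  x <- if (inherits(expr, "expr_matrix")) unclass_mat(expr) else expr
  mods <- setdiff(unique(assignment), "unassigned")
  if (!length(mods)) return(assignment)
  for (mm in mods) {
    members <- names(assignment)[assignment == mm]
    eig <- module_eigengene(x, members)
    kme <- apply(x[members, , drop = FALSE], 1, function(v)
      if (stats::sd(v) == 0) 0 else stats::cor(v, eig))
    assignment[members[kme < kme_min]] <- "unassigned"
  }
  grp <- match(assignment, setdiff(unique(assignment), "unassigned"))
  cl <- stats::setNames(ifelse(is.na(grp), 0L, grp) + 1L, names(assignment))
  lab <- relabel_modules(cl[cl > 1L], min_size)
  out <- stats::setNames(rep("unassigned", length(assignment)),
                         names(assignment))
  out[names(lab)] <- lab
  out
}

#' Correlate module eigengenes with TNM stage indicators
#'
#' Restricted to tumor samples with a non-missing TNM stage. Each
#' observed stage becomes a binary indicator column; `r` is the Pearson
#' correlation between the eigengene and the indicator, `p` two-sided
#' via t on `n - 2` df.
#'
#' @param eigengenes Module x sample matrix (from [detect_modules()]).
#' @param clinical A [clinical_table()].
#' @return List of class `module_trait_matrix` with matrices `r` and
#'   `p` (modules x stages) and `n_samples`.
#' @export
module_trait_correlation <- function(eigengenes, clinical) {
  cl <- clinical[clinical$condition == "tumor" & !is.na(clinical$tnm_stage), ]
  use <- intersect(colnames(eigengenes), cl$sample_id)
  if (length(use) < 3) stop("need >= 3 tumor samples with TNM stage")
  stage <- cl$tnm_stage[match(use, cl$sample_id)]
  stages <- intersect(c("I", "II", "III", "IV"), unique(stage))
  eg <- eigengenes[, use, drop = FALSE]
  r <- p <- matrix(NA_real_, nrow(eg), length(stages),
                   dimnames = list(rownames(eg), stages))
  nS <- length(use)
  for (s in stages) {
    ind <- as.numeric(stage == s)
    for (mm in rownames(eg)) {
      if (stats::sd(eg[mm, ]) == 0 || stats::sd(ind) == 0) next
      rr <- stats::cor(eg[mm, ], ind)
      r[mm, s] <- rr
      r2 <- min(rr^2, 1 - 1e-15)
      tt <- rr * sqrt((nS - 2) / (1 - r2))
      p[mm, s] <- 2 * stats::pt(-abs(tt), df = nS - 2)
    }
  }
  structure(list(r = r, p = p, n_samples = nS),
            class = "module_trait_matrix")
}

#' Modules significantly correlated with any TNM stage
#'
#' @param mt A `module_trait_matrix`.
#' @param p_max Strict p threshold (default 0.05).
#' @return Data.frame with columns `module`, `best_stage`, `best_r`,
#'   `best_p`, one row per significant module, ordered by `best_p`.
#' @export
significant_modules <- function(mt, p_max = 0.05) {
  if (!nrow(mt$p))
    return(data.frame(module = character(), best_stage = character(),
                      best_r = numeric(), best_p = numeric()))
  best_j <- apply(mt$p, 1, function(row)
    if (all(is.na(row))) NA_integer_ else which.min(row))
  best_p <- vapply(seq_len(nrow(mt$p)), function(i)
    if (is.na(best_j[i])) NA_real_ else mt$p[i, best_j[i]], 0)
  keep <- !is.na(best_p) & best_p < p_max
  out <- data.frame(
    module = rownames(mt$p)[keep],
    best_stage = colnames(mt$p)[best_j[keep]],
    best_r = vapply(which(keep), function(i) mt$r[i, best_j[i]], 0),
    best_p = best_p[keep], stringsAsFactors = FALSE)
  out[order(out$best_p, out$module), , drop = FALSE]
}
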