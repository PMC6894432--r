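# Paired tumor/normal cohort simulator with planted ground truth. Counts
# are negative binomial around log-normal baselines; differential genes
# shift tumor means by +/- de_log2fc; co-expression modules follow shared
# latent factors; ceRNA triplets are realized jointly in the target table
# and the expression layers; survival risk is tied to planted lncRNAs.

#' Configuration for the synthetic paired cohort
#'
#' Defaults emulate the screening study's cohort scale: 50 tumor/normal
#' pairs, a few thousand genes, planted log2 fold changes of 2, five
#' latent-factor lncRNA modules of 40 genes (the first driven by TNM
#' stage), and 80 planted ceRNA lncRNA-mRNA pairs each sharing two
#' miRNAs, of which 8 lncRNAs are "candidate" hubs carrying several pairs
#' and 2 of those carry a survival hazard.
#'
#' @param n_pairs Tumor/normal pairs (default 50).
#' @param n_mrna,n_lncrna,n_mirna Gene counts per role.
#' @param frac_de Fraction of each role's genes planted differentially
#'   expressed.
#' @param de_log2fc Magnitude of the planted tumor-vs-normal log2 fold
#'   change.
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param n_modules,module_size Planted lncRNA co-expression modules.
#' @param module_noise_sd Per-gene residual noise (log2 scale) around the
#'   module latent factor.
#' @param n_triplets Planted ceRNA lncRNA-mRNA pairs; each is realized
#'   with two shared miRNAs drawn from `n_triplet_mirnas` dedicated DE
#'   miRNAs (a single shared regulator is statistically
#'   indistinguishable from chance in a top/bottom-k miRNA universe).
#' @param n_triplet_mirnas Even number of dedicated triplet miRNAs (half
#'   planted up, half down so a top/bottom-10 screen retains all).
#' @param n_candidate_lnc Candidate hub lncRNAs (members of the trait
#'   module, each carrying `triplets_per_candidate` pairs).
#' @param triplets_per_candidate ceRNA pairs per candidate lncRNA.
#' @param n_risk_lnc Candidates whose high expression raises the death
#'   hazard.
#' @param risk_hr Hazard ratio per high-expression risk lncRNA.
#' @param surv_median_days Baseline median survival (days).
#' @param targets_per_mirna Mean out-degree of the emitted target table.
#' @param decoy_edge_frac Fraction of the target table that is random
#'   non-functional edges.
#' @param trait_effect Correlation strength between the trait module's
#'   latent factor and (standardized) TNM stage in tumors.
#' @param library_sd Log2-sd of per-sample library-size effects.
#' @param mirna_drop_one_pair If `TRUE`, the miRNA matrix omits the last
#'   tumor/normal pair (a 49-pair miRNA / 50-pair RNA cohort).
#' @param seed Integer seed governing the single root generator.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 50,
                          n_mrna = 2000, n_lncrna = 500, n_mirna = 150,
                          frac_de = 0.10, de_log2fc = 2,
                          nb_dispersion = 0.05,
                          n_modules = 5, module_size = 40,
                          module_noise_sd = 0.3,
                          n_triplets = 80, n_triplet_mirnas = 12,
                          n_candidate_lnc = 8, triplets_per_candidate = 5,
                          n_risk_lnc = 2, risk_hr = 2.5,
                          surv_median_days = 1000,
                          targets_per_mirna = 20, decoy_edge_frac = 0.9,
                          trait_effect = 0.7, library_sd = 0.15,
                          mirna_drop_one_pair = FALSE,
                          seed = 1) {
  cfg <- as.list(environment())
  pos <- c("n_pairs", "n_mrna", "n_lncrna", "n_mirna",
           "module_size", "targets_per_mirna", "surv_median_days")
  for (f in pos) if (cfg[[f]] <= 0) stop(f, " must be positive")
  if (n_modules < 0) stop("n_modules must be >= 0")
  if (n_modules == 0 && n_triplets > 0 && n_candidate_lnc > 0)
    stop("candidate lncRNAs need at least one planted module (their trait module)")
  for (f in c("frac_de", "decoy_edge_frac"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (de_log2fc <= 0) stop("de_log2fc must be > 0")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (module_noise_sd < 0) stop("module_noise_sd must be >= 0")
  if (n_modules * module_size > n_lncrna)
    stop("module_size x n_modules exceeds n_lncrna (",
         n_modules * module_size, " > ", n_lncrna, ")")
  if (n_triplet_mirnas %% 2 != 0) stop("n_triplet_mirnas must be even")
  if (n_triplets > 0) {
    if (n_candidate_lnc * triplets_per_candidate > n_triplets)
      stop("n_candidate_lnc x triplets_per_candidate exceeds n_triplets")
    n_de_lnc <- round(frac_de * n_lncrna)
    n_bg <- n_triplets - n_candidate_lnc * triplets_per_candidate
    if (n_candidate_lnc + n_bg > n_de_lnc)
      stop("planted triplet lncRNAs (", n_candidate_lnc + n_bg,
           ") exceed the DE lncRNA quota (", n_de_lnc,
           "); raise frac_de or lower n_triplets")
    if (n_triplets > round(frac_de * n_mrna))
      stop("planted triplet mRNAs exceed the DE mRNA quota")
    if (n_triplet_mirnas > round(frac_de * n_mirna))
      stop("n_triplet_mirnas exceeds the DE miRNA quota")
    if (n_risk_lnc > n_candidate_lnc)
      stop("n_risk_lnc exceeds n_candidate_lnc")
    if (choose(n_triplet_mirnas, 2) < n_candidate_lnc)
      stop("too few triplet miRNA duos for distinct candidate assignments")
  }
  if (trait_effect < 0 || trait_effect > 1)
    stop("trait_effect must be in [0, 1]")
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic paired cohort with planted ground truth
#'
#' Produces count matrices for mRNA, lncRNA and miRNA, a clinical table
#' (pairing, TNM stage on tumors, survival follow-up), an RNA22-style
#' miRNA-to-target edge table, and a `ground_truth` record of everything
#' planted. Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List with elements `mrna`, `lncrna`, `mirna`
#'   ([expression_matrix()] of counts), `clinical`
#'   ([clinical_table()]), `targets` ([target_edge_table()]) and `truth`
#'   (class `ground_truth`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  set.seed(cf$seed)

  pid <- sprintf("P%03d", seq_len(cf$n_pairs))
  sid_t <- paste0(pid, "_T"); sid_n <- paste0(pid, "_N")
  sid <- c(rbind(sid_t, sid_n))
  cond <- rep(c("tumor", "normal"), cf$n_pairs)
  n_s <- length(sid)
  is_tumor <- cond == "tumor"

  mrna_ids <- sprintf("MRNA%04d", seq_len(cf$n_mrna))
  lnc_ids <- sprintf("LNC%04d", seq_len(cf$n_lncrna))
  mir_ids <- sprintf("MIR%04d", seq_len(cf$n_mirna))

  tnm <- sample(c("I", "II", "III"), cf$n_pairs, replace = TRUE)

  ## ---- planted structure ------------------------------------------------
  n_cand_pairs <- if (cf$n_triplets > 0)
    cf$n_candidate_lnc * cf$triplets_per_candidate else 0L
  n_bg_pairs <- cf$n_triplets - n_cand_pairs
  n_cand <- if (cf$n_triplets > 0) cf$n_candidate_lnc else 0L

  module_genes <- if (cf$n_modules * cf$module_size > 0)
    lnc_ids[seq_len(cf$n_modules * cf$module_size)] else character()
  module_of <- rep(sprintf("M%d", seq_len(cf$n_modules)),
                   each = cf$module_size)[seq_along(module_genes)]
  trait_module <- if (cf$n_modules >= 1) "M1" else character()
  candidates <- if (n_cand > 0) module_genes[module_of == trait_module][seq_len(n_cand)]
                else character()

  free_lnc <- setdiff(lnc_ids, module_genes)
  bg_lnc <- if (n_bg_pairs > 0) free_lnc[seq_len(n_bg_pairs)] else character()

  pair_lnc <- c(rep(candidates, each = cf$triplets_per_candidate), bg_lnc)
  pair_mrna <- if (cf$n_triplets > 0) mrna_ids[seq_len(cf$n_triplets)]
               else character()
  trip_mirs <- if (cf$n_triplets > 0) mir_ids[seq_len(cf$n_triplet_mirnas)]
               else character()
  # Each lncRNA sponges one dedicated miRNA duo shared by all its
  # partners (so a hub's per-pair overlap m equals its universe
  # out-degree K and stays enriched); candidate duos are distinct.
  pair_mir <- vector("list", cf$n_triplets)
  if (cf$n_triplets > 0) {
    duos <- utils::combn(trip_mirs, 2, simplify = FALSE)
    cand_duos <- sample(duos, n_cand)
    for (i in seq_len(cf$n_triplets)) {
      pair_mir[[i]] <- if (i <= n_cand_pairs)
        sort(cand_duos[[ceiling(i / cf$triplets_per_candidate)]])
      else sort(sample(trip_mirs, 2))
    }
  }

  ## ---- differential expression plan -------------------------------------
  plan_de <- function(ids, quota, forced, forced_sign) {
    sel <- forced
    extra <- setdiff(ids, forced)
    n_extra <- max(0, quota - length(forced))
    extra <- if (n_extra > 0) sample(extra, n_extra) else character()
    sign <- c(forced_sign, sample(c(-1, 1), length(extra), replace = TRUE))
    data.frame(gene_id = c(sel, extra), sign = sign,
               stringsAsFactors = FALSE)
  }
  half <- cf$n_triplet_mirnas / 2
  de_mrna <- plan_de(mrna_ids, round(cf$frac_de * cf$n_mrna),
                     pair_mrna, rep(1, length(pair_mrna)))
  trip_lnc <- unique(pair_lnc)
  de_lnc <- plan_de(lnc_ids, round(cf$frac_de * cf$n_lncrna),
                    trip_lnc, rep(1, length(trip_lnc)))
  de_mir <- plan_de(mir_ids, round(cf$frac_de * cf$n_mirna),
                    trip_mirs, rep(c(1, -1), c(half, half))[seq_along(trip_mirs)])

  ## ---- target table ------------------------------------------------------
  planted_edges <- if (cf$n_triplets > 0) rbind(
    data.frame(mirna_id = unlist(pair_mir),
               target_id = rep(pair_lnc, each = 2),
               stringsAsFactors = FALSE),
    data.frame(mirna_id = unlist(pair_mir),
               target_id = rep(pair_mrna, each = 2),
               stringsAsFactors = FALSE))
  else data.frame(mirna_id = character(), target_id = character(),
                  stringsAsFactors = FALSE)
  n_decoy <- round(cf$decoy_edge_frac * cf$targets_per_mirna * cf$n_mirna)
  all_targets <- c(mrna_ids, lnc_ids)
  decoys <- data.frame(
    mirna_id = sample(mir_ids, n_decoy, replace = TRUE),
    target_id = sample(all_targets, n_decoy, replace = TRUE),
    stringsAsFactors = FALSE)
  targets <- target_edge_table(rbind(planted_edges, decoys))

  ## ---- latent factors ----------------------------------------------------
  factors <- matrix(stats::rnorm(cf$n_modules * n_s), cf$n_modules, n_s,
                    dimnames = list(sprintf("M%d", seq_len(cf$n_modules)), sid))
  if (cf$trait_effect > 0 && cf$n_modules >= 1) {
    st_num <- match(tnm, c("I", "II", "III"))
    z <- as.numeric(scale(st_num))
    if (all(is.finite(z)))
      factors[trait_module, sid_t] <-
        cf$trait_effect * z +
        sqrt(1 - cf$trait_effect^2) * stats::rnorm(cf$n_pairs)
  }
  pair_factor <- matrix(0, max(1, cf$n_triplets), n_s)
  if (cf$n_triplets > 0) {
    for (i in seq_len(cf$n_triplets)) {
      pair_factor[i, ] <- if (i <= n_cand_pairs) factors[trait_module, ]
                          else stats::rnorm(n_s)
    }
  }

  ## ---- expression means and counts --------------------------------------
  lib <- stats::rnorm(n_s, 0, cf$library_sd)
  shift_mat <- function(ids, de) {
    s <- numeric(length(ids)); names(s) <- ids
    s[de$gene_id] <- de$sign * cf$de_log2fc
    s
  }
  draw_counts <- function(ids, base_mean, base_sd, de, extra_log2) {
    base <- pmin(pmax(stats::rnorm(length(ids), base_mean, base_sd), 3), 12)
    sh <- shift_mat(ids, de)
    logmu <- outer(base, lib, "+") +
      outer(sh, as.numeric(is_tumor), "*") + extra_log2
    mu <- 2^logmu
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / cf$nb_dispersion),
                  nrow = length(ids), dimnames = list(ids, sid))
    cnt
  }

  extra_mrna <- matrix(0, cf$n_mrna, n_s, dimnames = list(mrna_ids, sid))
  if (cf$n_triplets > 0)
    for (i in seq_len(cf$n_triplets))
      extra_mrna[pair_mrna[i], ] <- extra_mrna[pair_mrna[i], ] + pair_factor[i, ]

  extra_lnc <- matrix(0, cf$n_lncrna, n_s, dimnames = list(lnc_ids, sid))
  if (length(module_genes)) {
    extra_lnc[module_genes, ] <- factors[module_of, , drop = FALSE] +
      matrix(stats::rnorm(length(module_genes) * n_s, 0, cf$module_noise_sd),
             length(module_genes), n_s)
  }
  if (n_bg_pairs > 0)
    for (i in seq_len(n_bg_pairs))
      extra_lnc[bg_lnc[i], ] <- extra_lnc[bg_lnc[i], ] +
        pair_factor[n_cand_pairs + i, ]

  extra_mir <- matrix(0, cf$n_mirna, n_s, dimnames = list(mir_ids, sid))
  if (cf$n_triplets > 0) {
    assoc <- lapply(trip_mirs, function(m)
      which(vapply(pair_mir, function(p) m %in% p, TRUE)))
    names(assoc) <- trip_mirs
    for (m in trip_mirs) {
      idx <- assoc[[m]]
      if (length(idx))
        extra_mir[m, ] <- -colSums(pair_factor[idx, , drop = FALSE]) /
          sqrt(length(idx))
    }
  }

  mrna <- expression_matrix(draw_counts(mrna_ids, 6, 1.2, de_mrna, extra_mrna),
                            "mRNA", "counts")
  lncrna <- expression_matrix(draw_counts(lnc_ids, 6, 1.2, de_lnc, extra_lnc),
                              "lncRNA", "counts")
  mirna_full <- draw_counts(mir_ids, 7, 1.0, de_mir, extra_mir)
  if (cf$mirna_drop_one_pair && cf$n_pairs > 1)
    mirna_full <- mirna_full[, !(sid %in% c(sid_t[cf$n_pairs],
                                            sid_n[cf$n_pairs])), drop = FALSE]
  mirna <- expression_matrix(mirna_full, "miRNA", "counts")

  ## ---- survival ----------------------------------------------------------
  risk_lnc <- if (cf$n_triplets > 0 && cf$n_risk_lnc > 0)
    candidates[seq_len(cf$n_risk_lnc)] else character()
  log2_t <- log2(unclass_mat(lncrna)[, sid_t, drop = FALSE] + 0.5)
  n_top <- integer(cf$n_pairs)
  for (g in risk_lnc) {
    top <- rank(log2_t[g, ], ties.method = "first") > cf$n_pairs / 2
    n_top <- n_top + as.integer(top)
  }
  base_rate <- log(2) / cf$surv_median_days
  t_ev <- stats::rexp(cf$n_pairs, rate = base_rate * cf$risk_hr^n_top)
  t_cn <- stats::runif(cf$n_pairs, 365, 2500)
  surv_time <- round(pmin(t_ev, t_cn), 1)
  event <- as.integer(t_ev <= t_cn)

  clinical <- clinical_table(data.frame(
    sample_id = sid,
    patient_id = rep(pid, each = 2),
    condition = cond,
    pair_id = rep(pid, each = 2),
    tnm_stage = ifelse(is_tumor, rep(tnm, each = 2), NA),
    survival_time = ifelse(is_tumor, rep(surv_time, each = 2), NA),
    event = ifelse(is_tumor, rep(event, each = 2), NA),
    stringsAsFactors = FALSE))

  truth <- structure(list(
    de = rbind(
      data.frame(role = rep("mRNA", nrow(de_mrna)), gene_id = de_mrna$gene_id,
                 log2fc = de_mrna$sign * cf$de_log2fc),
      data.frame(role = rep("lncRNA", nrow(de_lnc)), gene_id = de_lnc$gene_id,
                 log2fc = de_lnc$sign * cf$de_log2fc),
      data.frame(role = rep("miRNA", nrow(de_mir)), gene_id = de_mir$gene_id,
                 log2fc = de_mir$sign * cf$de_log2fc)),
    modules = data.frame(gene_id = module_genes, module = module_of,
                         stringsAsFactors = FALSE),
    trait_module = trait_module,
    triplets = if (cf$n_triplets > 0) data.frame(
      lncrna_id = rep(pair_lnc, each = 2),
      mirna_id = unlist(pair_mir),
      mrna_id = rep(pair_mrna, each = 2),
      stringsAsFactors = FALSE)
    else data.frame(lncrna_id = character(), mirna_id = character(),
                    mrna_id = character()),
    pairs = data.frame(lncrna_id = pair_lnc, mrna_id = pair_mrna,
                       stringsAsFactors = FALSE),
    candidates = candidates,
    risk_lncrnas = risk_lnc,
    factors = factors), class = "ground_truth")
  rownames(truth$de) <- NULL

  list(mrna = mrna, lncrna = lncrna, mirna = mirna,
       clinical = clinical, targets = targets, truth = truth)
}

#' Dump planted ground truth to a long-format TSV
#'
#' Sections (`part` column): `de` (role, gene, log2fc), `module`,
#' `trait_module`, `triplet`, `pair`, `candidate`, `risk`, `factor`
#' (module, sample, value). [read_truth_report()] reconstructs the
#' record.
#'
#' @param truth A `ground_truth` from [generate_cohort()].
#' @param path Output path.
#' @export
truth_report <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  part_df <- function(part, a, b = "", c = "") {
    n <- length(a)
    data.frame(part = rep(part, n), a = a,
               b = if (length(b) == n) b else rep(b, n),
               c = if (length(c) == n) c else rep(c, n),
               stringsAsFactors = FALSE)
  }
  rows <- list(
    part_df("de", truth$de$role, truth$de$gene_id,
            as.character(truth$de$log2fc)),
    part_df("module", truth$modules$gene_id, truth$modules$module),
    part_df("trait_module", truth$trait_module),
    part_df("triplet", truth$triplets$lncrna_id, truth$triplets$mirna_id,
            truth$triplets$mrna_id),
    part_df("pair", truth$pairs$lncrna_id, truth$pairs$mrna_id),
    part_df("candidate", truth$candidates),
    part_df("risk", truth$risk_lncrnas),
    part_df("factor",
            rep(rownames(truth$factors), ncol(truth$factors)),
            rep(colnames(truth$factors), each = nrow(truth$factors)),
            as.character(as.vector(truth$factors))))
  rows <- rows[vapply(rows, nrow, 0L) > 0]
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(part = character(), a = character(),
                        b = character(), c = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a [truth_report()] TSV
#' @param path Path written by [truth_report()].
#' @return A `ground_truth` list.
#' @export
read_truth_report <- function(path) {
  df <- read_tsv_strict(path)
  pick <- function(p) df[df$part == p, , drop = FALSE]
  de <- pick("de"); mo <- pick("module"); tr <- pick("triplet")
  pr <- pick("pair"); fa <- pick("factor")
  factors <- NULL
  if (nrow(fa)) {
    mods <- unique(fa$a); samps <- unique(fa$b)
    factors <- matrix(as.numeric(fa$c), length(mods), length(samps),
                      dimnames = list(mods, samps))
  }
  structure(list(
    de = data.frame(role = de$a, gene_id = de$b, log2fc = as.numeric(de$c),
                    stringsAsFactors = FALSE),
    modules = data.frame(gene_id = mo$a, module = mo$b,
                         stringsAsFactors = FALSE),
    trait_module = if (nrow(pick("trait_module"))) pick("trait_module")$a
                   else character(),
    triplets = data.frame(lncrna_id = tr$a, mirna_id = tr$b, mrna_id = tr$c,
                          stringsAsFactors = FALSE),
    pairs = data.frame(lncrna_id = pr$a, mrna_id = pr$b,
                       stringsAsFactors = FALSE),
    candidates = pick("candidate")$a,
    risk_lncrnas = pick("risk")$a,
    factors = factors), class = "ground_truth")
}

#' Build a synthetic gene-set collection around planted ceRNA targets
#'
#' One set per planted candidate lncRNA (its partner mRNAs padded with
#' random mRNAs) plus random decoy sets, so the over-representation stage
#' has both signal and null sets to score. Draws from the current RNG
#' stream.
#'
#' @param truth A `ground_truth`.
#' @param mrna_ids Universe of mRNA ids.
#' @param n_random Number of random decoy sets.
#' @param set_size Target set size.
#' @return A [gene_set_collection()].
#' @export
generate_gene_sets <- function(truth, mrna_ids, n_random = 15,
                               set_size = 25) {
  sets <- list()
  desc <- character()
  for (cand in truth$candidates) {
    members <- unique(truth$pairs$mrna_id[truth$pairs$lncrna_id == cand])
    pad <- setdiff(mrna_ids, members)
    extra <- sample(pad, max(0, set_size - length(members)))
    sets[[paste0("SET_", cand)]] <- c(members, extra)
    desc <- c(desc, paste0("partners of ", cand, " plus padding"))
  }
  for (i in seq_len(n_random)) {
    sets[[sprintf("SET_RANDOM%02d", i)]] <- sample(mrna_ids, set_size)
    desc <- c(desc, "random decoy set")
  }
  gene_set_collection(sets, descriptions = desc)
}
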