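# End-to-end orchestration: one structured config drives
# simulate -> de -> cerna -> wgcna -> select -> survival -> enrich,
# writing every intermediate TSV plus a run manifest. Identical
# config + seed reproduces identical outputs.

.CONFIG_RANGES <- list(
  fdr_max = c(0, 1), min_abs_log2fc = c(0, Inf), mirna_top_k = c(1, Inf),
  prior = c(0, Inf), hyper_p_max = c(0, 1), pcc_p_max = c(0, 1),
  coexp_pcc_min = c(-1, 1), degree_fraction = c(0, 1),
  module_p_max = c(0, 1), r2_min = c(-1, 1), cut_height = c(0, 1),
  min_module_size = c(2, Inf), merge_diss_max = c(0, 1), seed = c(-Inf, Inf))

#' Default pipeline configuration
#'
#' All stage thresholds in one auditable place: FDR < 0.01 and
#' |log2FC| > 1 for mRNA/lncRNA selection, top/bottom-10 miRNAs,
#' hypergeometric and correlation p < 0.05, co-expression PCC >= 0.7,
#' top-20% ceRNA degree, module-trait p < 0.05, plus the WGCNA
#' parameters. The `simulate` block is a [cohort_config()]; supply
#' `inputs` (paths to expression/clinical/target TSVs) instead to run on
#' real data.
#'
#' @param seed Integer seed (also forwarded to the simulate block).
#' @param outdir Output directory for stage TSVs and the manifest.
#' @param ... Overrides for any top-level threshold field.
#' @return List of class `run_config`.
#' @export
default_run_config <- function(seed = 1, outdir = tempfile("cernarun"),
                               ...) {
  cfg <- list(
    seed = seed, outdir = outdir,
    simulate = cohort_config(seed = seed),
    inputs = NULL, gmt = NULL,
    fdr_max = 0.01, min_abs_log2fc = 1, mirna_top_k = 10, prior = 0.5,
    hyper_p_max = 0.05, pcc_p_max = 0.05,
    coexp_pcc_min = 0.7, degree_fraction = 0.20, module_p_max = 0.05,
    powers = c(6:10, 12, 14, 16), r2_min = 0.85,
    cut_height = 0.985, min_module_size = 30, merge_diss_max = 0.25)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Accepts a `run_config`, a plain list, or a path to a YAML file.
#' Every violation (unknown keys, out-of-range thresholds) is reported
#' at once.
#'
#' @param config Config object or YAML path.
#' @return The validated `run_config` (invisibly re-classed), or an
#'   error listing all violations.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    raw <- yaml::read_yaml(config)
    if (!is.null(raw$simulate))
      raw$simulate <- do.call(cohort_config, raw$simulate)
    config <- raw
  }
  tmpl <- names(formals(default_run_config))
  known <- c("seed", "outdir", "simulate", "inputs", "gmt",
             names(.CONFIG_RANGES), "powers")
  errs <- character()
  bad <- setdiff(names(config), known)
  if (length(bad))
    errs <- c(errs, paste0("unknown key(s): ", paste(bad, collapse = ", ")))
  for (f in names(.CONFIG_RANGES)) {
    v <- config[[f]]
    if (is.null(v)) { errs <- c(errs, paste0("missing field: ", f)); next }
    rng <- .CONFIG_RANGES[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) ||
        v < rng[1] || v > rng[2])
      errs <- c(errs, sprintf("%s = %s outside [%s, %s]", f,
                              paste(v, collapse = ","), rng[1], rng[2]))
  }
  if (is.null(config$simulate) && is.null(config$inputs))
    errs <- c(errs, "config needs a 'simulate' block or 'inputs' paths")
  if (!is.null(config$powers) &&
      (!is.numeric(config$powers) || any(config$powers <= 0)))
    errs <- c(errs, "powers must be positive numbers")
  if (length(errs))
    stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "))
  class(config) <- "run_config"
  invisible(config)
}

write_stage_tsv <- function(df, outdir, name) {
  path <- file.path(outdir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  nrow(df)
}

#' Run the full screening pipeline from one configuration
#'
#' Executes simulate (or input loading), differential expression, ceRNA
#' inference, weighted co-expression module detection with TNM
#' correlation, candidate selection, survival screening and
#' over-representation analysis, writing each stage's table under
#' `config$outdir` and returning a manifest of row counts. Identical
#' config + seed yields byte-identical outputs.
#'
#' @param config A `run_config` from [default_run_config()] /
#'   [validate_config()].
#' @param quiet Suppress per-stage messages (default `TRUE`).
#' @return List of class `run_manifest`: `seed`, `thresholds`, `stages`
#'   (data.frame of stage, output, rows) and `results` (the in-memory
#'   stage objects).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  config <- validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  man <- list()
  log_stage <- function(stage, output, rows)
    man[[length(man) + 1]] <<- data.frame(stage = stage, output = output,
                                          rows = rows)
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## stage 1: cohort --------------------------------------------------------
  cohort <- wrap("simulate", {
    if (!is.null(config$inputs)) {
      inp <- config$inputs
      list(mrna = read_expression_matrix(inp$mrna, "mRNA", "counts"),
           lncrna = read_expression_matrix(inp$lncrna, "lncRNA", "counts"),
           mirna = read_expression_matrix(inp$mirna, "miRNA", "counts"),
           clinical = read_clinical_table(inp$clinical),
           targets = read_target_edges(inp$targets),
           truth = NULL)
    } else {
      generate_cohort(config$simulate)
    }
  })
  set.seed(config$seed + 1L)  # post-simulation stream for downstream draws
  for (nm in c("mrna", "lncrna", "mirna"))
    write_expression_matrix(cohort[[nm]], file.path(config$outdir,
                                                    paste0(nm, "_counts.tsv")))
  write_clinical_table(cohort$clinical, file.path(config$outdir,
                                                  "clinical.tsv"))
  write_target_edges(cohort$targets, file.path(config$outdir,
                                               "target_edges.tsv"))
  if (!is.null(cohort$truth))
    truth_report(cohort$truth, file.path(config$outdir, "ground_truth.tsv"))
  log_stage("simulate", "clinical.tsv", nrow(cohort$clinical))
  say("cohort: ", ncol(cohort$mrna), " samples")

  tumor_ids <- cohort$clinical$sample_id[cohort$clinical$condition == "tumor"]

  ## stage 2: differential expression --------------------------------------
  de <- wrap("de", {
    norm <- lapply(cohort[c("mrna", "lncrna", "mirna")], function(m)
      to_log2cpm(m, tmm_factors(m), prior = config$prior))
    tests <- lapply(norm, function(m)
      suppressWarnings(paired_de_test(m, cohort$clinical)))
    sel <- list(
      mrna = select_de_genes(tests$mrna, config$fdr_max,
                             config$min_abs_log2fc),
      lncrna = select_de_genes(tests$lncrna, config$fdr_max,
                               config$min_abs_log2fc),
      mirna = select_top_bottom_mirnas(tests$mirna, config$mirna_top_k))
    list(log2cpm = norm, tests = tests, selected = sel)
  })
  for (nm in names(de$tests)) {
    tab <- de$tests[[nm]]
    tab$selected <- tab$gene_id %in% de$selected[[nm]]
    write_stage_tsv(tab, config$outdir, paste0("de_", nm))
  }
  log_stage("de", "de_mrna.tsv",
            sum(lengths(de$selected)))
  say("DE selected: ", paste(names(de$selected), lengths(de$selected),
                             sep = "=", collapse = " "))

  ## stage 3: ceRNA ---------------------------------------------------------
  cerna <- wrap("cerna", {
    universe <- intersect(de$selected$mirna, unique(cohort$targets$mirna_id))
    pairs <- shared_mirna_table(cohort$targets, de$selected$lncrna,
                                de$selected$mrna, universe)
    passing <- if (nrow(pairs))
      filter_cerna_pairs(pairs, de$log2cpm$lncrna, de$log2cpm$mrna,
                         sample_ids = tumor_ids,
                         hyper_p_max = config$hyper_p_max,
                         pcc_p_max = config$pcc_p_max)
      else { attr(pairs, "all_pairs") <- pairs; pairs }
    network <- build_cerna_network(passing, include_mirna_nodes = TRUE)
    cent <- if (nrow(network$nodes)) centralities(network) else
      data.frame(id = character(), type = character(), degree = numeric(),
                 betweenness = numeric(), closeness = numeric())
    top_mirnas <- rank_network_mirnas(network, de$tests$mirna, k = 20)
    list(pairs = attr(passing, "all_pairs"), passing = passing,
         network = network, centralities = cent, top_mirnas = top_mirnas)
  })
  write_stage_tsv(as.data.frame(cerna$pairs), config$outdir, "cerna_pairs")
  write_edge_list(cerna$network, file.path(config$outdir, "cerna_network.sif"))
  write_stage_tsv(cerna$centralities, config$outdir, "cerna_centralities")
  log_stage("cerna", "cerna_pairs.tsv", nrow(cerna$passing))
  say("ceRNA: ", nrow(cerna$passing), " passing pairs of ",
      nrow(cerna$pairs), " candidates")

  ## stage 4: weighted co-expression modules --------------------------------
  wgcna <- wrap("wgcna", {
    expr <- unclass_mat(de$log2cpm$lncrna)[, tumor_ids, drop = FALSE]
    expr <- expr[apply(expr, 1, stats::sd) > 0, , drop = FALSE]
    scan <- suppressWarnings(
      pick_soft_threshold(expr, config$powers, config$r2_min))
    adj <- signed_adjacency(stats::cor(t(expr)), scan$chosen_power)
    tom <- topological_overlap(adj)
    mods <- detect_modules(1 - tom, config$min_module_size,
                           config$cut_height, config$merge_diss_max,
                           expr = expr)
    mt <- if (!is.null(mods$eigengenes))
      module_trait_correlation(mods$eigengenes, cohort$clinical) else NULL
    sig <- if (!is.null(mt)) significant_modules(mt, config$module_p_max)
           else data.frame(module = character(), best_stage = character(),
                           best_r = numeric(), best_p = numeric())
    list(scan = scan, modules = mods, trait = mt, significant = sig)
  })
  write_stage_tsv(data.frame(gene_id = names(wgcna$modules$assignment),
                             module = unname(wgcna$modules$assignment)),
                  config$outdir, "module_assignment")
  if (!is.null(wgcna$modules$eigengenes))
    write_stage_tsv(data.frame(module = rownames(wgcna$modules$eigengenes),
                               wgcna$modules$eigengenes, check.names = FALSE),
                    config$outdir, "module_eigengenes")
  if (!is.null(wgcna$trait)) {
    mt_df <- data.frame(module = rownames(wgcna$trait$r),
                        stage = rep(colnames(wgcna$trait$r),
                                    each = nrow(wgcna$trait$r)),
                        r = as.vector(wgcna$trait$r),
                        p = as.vector(wgcna$trait$p))
    write_stage_tsv(mt_df, config$outdir, "module_trait")
  }
  n_mod <- sum(names(wgcna$modules$sizes) != "unassigned")
  log_stage("wgcna", "module_assignment.tsv", n_mod)
  say("modules: ", n_mod, " (power ", wgcna$scan$chosen_power, "), ",
      nrow(wgcna$significant), " TNM-significant")

  ## stage 5: candidate selection -------------------------------------------
  select <- wrap("select", {
    coexp <- build_coexpression_network(de$log2cpm$lncrna, de$log2cpm$mrna,
                                        config$coexp_pcc_min,
                                        sample_ids = tumor_ids)
    report <- suppressWarnings(
      select_candidates(cerna$network, wgcna$modules, wgcna$significant,
                        coexp, config$degree_fraction))
    list(coexp = coexp, report = report,
         targets = candidate_target_table(report))
  })
  write_stage_tsv(as.data.frame(select$coexp), config$outdir,
                  "coexpression_edges")
  write_stage_tsv(select$report$candidates, config$outdir, "candidates")
  write_stage_tsv(select$targets, config$outdir, "candidate_targets")
  log_stage("select", "candidates.tsv", nrow(select$report$candidates))
  say("candidates: ", nrow(select$report$candidates), ", ",
      attr(select$targets, "n_distinct_mrna"), " distinct target mRNAs")

  ## stage 6: survival --------------------------------------------------------
  surv <- wrap("survival", {
    survival_screen(select$report$candidates$lncrna_id, de$log2cpm$lncrna,
                    cohort$clinical)
  })
  write_stage_tsv(surv, config$outdir, "survival_screen")
  log_stage("survival", "survival_screen.tsv", sum(surv$flagged))

  ## stage 7: enrichment -------------------------------------------------------
  enr <- wrap("enrich", {
    sets <- if (!is.null(config$gmt)) read_gmt(config$gmt)
            else if (!is.null(cohort$truth))
              generate_gene_sets(cohort$truth, rownames(cohort$mrna))
            else NULL
    if (is.null(sets) || !nrow(select$targets)) NULL
    else ora(unique(select$targets$mrna_id), sets, rownames(cohort$mrna))
  })
  if (!is.null(enr)) write_stage_tsv(enr, config$outdir, "enrichment")
  log_stage("enrich", "enrichment.tsv",
            if (is.null(enr)) 0L else sum(enr$fdr < 0.05))

  stages <- do.call(rbind, man)
  manifest <- list(seed = config$seed,
                   thresholds = config[names(.CONFIG_RANGES)],
                   stages = stages,
                   results = list(cohort = cohort, de = de, cerna = cerna,
                                  wgcna = wgcna, select = select,
                                  survival = surv, enrichment = enr))
  utils::write.table(stages, file.path(config$outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest (seed ", x$seed, ")\n", sep = "")
  print(x$stages, row.names = FALSE)
  invisible(x)
}
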