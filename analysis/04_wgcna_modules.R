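#!/usr/bin/env Rscript
# Stage 4 — signed weighted co-expression modules and TNM correlation.
#
# Soft threshold by scale-free fit over a signed-network power grid,
# signed adjacency, topological overlap, average-linkage module
# detection (static cut, eigengene merging, kME pruning), module
# eigengenes, and eigengene-TNM-stage correlations on tumor samples.

suppressMessages(library(cernascreen))

outdir <- "results/wgcna"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

clin <- read_clinical_table("results/cohort/clinical.tsv")
tumor_ids <- clin$sample_id[clin$condition == "tumor"]
expr <- read_expression_matrix("results/de/lncrna_log2cpm.tsv",
                               "lncRNA", "log2CPM")
x <- unclass(expr)[, tumor_ids]
x <- x[apply(x, 1, sd) > 0, ]

scan <- suppressWarnings(pick_soft_threshold(x, powers = c(6:10, 12, 14, 16)))
adj <- signed_adjacency(cor(t(x)), scan$chosen_power)
tom <- topological_overlap(adj)
mods <- detect_modules(1 - tom, min_module_size = 30, cut_height = 0.985,
                       merge_diss_max = 0.25, expr = x)
mt <- module_trait_correlation(mods$eigengenes, clin)
sig <- significant_modules(mt, p_max = 0.05)

write.table(scan$scan, file.path(outdir, "soft_threshold_scan.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = names(mods$assignment),
                       module = unname(mods$assignment)),
            file.path(outdir, "module_assignment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(module = rownames(mods$eigengenes),
                       mods$eigengenes, check.names = FALSE),
            file.path(outdir, "module_eigengenes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(module = rownames(mt$r),
                       stage = rep(colnames(mt$r), each = nrow(mt$r)),
                       r = as.vector(mt$r), p = as.vector(mt$p)),
            file.path(outdir, "module_trait.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sig, file.path(outdir, "significant_modules.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("soft power %d; %d modules (sizes: %s); %d unassigned\n",
            scan$chosen_power,
            sum(names(mods$sizes) != "unassigned"),
            paste(mods$sizes[names(mods$sizes) != "unassigned"],
                  collapse = ", "),
            sum(mods$assignment == "unassigned")))
if (nrow(sig))
  cat(sprintf("TNM-significant: %s (best p = %.2g at stage %s)\n",
              paste(sig$module, collapse = ", "), sig$best_p[1],
              sig$best_stage[1]))
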