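#!/usr/bin/env Rscript
# Stage 5 — candidate lncRNA nomination.
#
# Intersects three layers: top-20%-degree lncRNAs of the ceRNA pair
# graph, membership in a TNM-significant module, and >= 1 co-expression
# edge at PCC >= 0.7 (tumor samples).

suppressMessages(library(cernascreen))

outdir <- "results/select"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

clin <- read_clinical_table("results/cohort/clinical.tsv")
tumor_ids <- clin$sample_id[clin$condition == "tumor"]
expr_lnc <- read_expression_matrix("results/de/lncrna_log2cpm.tsv",
                                   "lncRNA", "log2CPM")
expr_mrna <- read_expression_matrix("results/de/mrna_log2cpm.tsv",
                                    "mRNA", "log2CPM")
pairs_all <- read.delim("results/cerna/cerna_pairs.tsv")
passing <- pairs_all[pairs_all$passes, ]
class(passing) <- c("cerna_pairs", "data.frame")
net <- build_cerna_network(passing, include_mirna_nodes = TRUE)

assign_df <- read.delim("results/wgcna/module_assignment.tsv")
modules <- structure(list(assignment = setNames(assign_df$module,
                                                assign_df$gene_id)),
                     class = "module_set")
sig <- read.delim("results/wgcna/significant_modules.tsv")

coexp <- build_coexpression_network(expr_lnc, expr_mrna, pcc_min = 0.7,
                                    sample_ids = tumor_ids)
report <- select_candidates(net, modules, sig, coexp, fraction = 0.20)
targets <- candidate_target_table(report)

write.table(as.data.frame(coexp), file.path(outdir, "coexpression_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(report$candidates, file.path(outdir, "candidates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(targets, file.path(outdir, "candidate_targets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("co-expression edges: %d; candidates: %d; distinct target mRNAs: %d\n",
            nrow(coexp), nrow(report$candidates),
            attr(targets, "n_distinct_mrna")))
print(report$candidates, row.names = FALSE)
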