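#!/usr/bin/env Rscript
# Stage 3 — ceRNA pair inference and network construction.
#
# Candidate lncRNA-mRNA pairs share >= 1 DE miRNA from the predicted
# target table; pairs pass with hypergeometric p < 0.05, positive tumor
# PCC, and correlation p < 0.05. Node centralities (degree, betweenness,
# closeness) are computed on the mixed network.

suppressMessages(library(cernascreen))

outdir <- "results/cerna"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

targets <- read_target_edges("results/cohort/target_edges.tsv")
clin <- read_clinical_table("results/cohort/clinical.tsv")
tumor_ids <- clin$sample_id[clin$condition == "tumor"]

de <- lapply(c(mrna = "mrna", lncrna = "lncrna", mirna = "mirna"),
             function(r) read.delim(sprintf("results/de/de_%s.tsv", r)))
expr_lnc <- read_expression_matrix("results/de/lncrna_log2cpm.tsv",
                                   "lncRNA", "log2CPM")
expr_mrna <- read_expression_matrix("results/de/mrna_log2cpm.tsv",
                                    "mRNA", "log2CPM")

universe <- intersect(de$mirna$gene_id[de$mirna$selected],
                      unique(targets$mirna_id))
pairs <- shared_mirna_table(targets,
                            de$lncrna$gene_id[de$lncrna$selected],
                            de$mrna$gene_id[de$mrna$selected], universe)
passing <- filter_cerna_pairs(pairs, expr_lnc, expr_mrna,
                              sample_ids = tumor_ids)
net <- build_cerna_network(passing, include_mirna_nodes = TRUE)
cent <- centralities(net)
top_mirnas <- rank_network_mirnas(net, de$mirna, k = 20)

write.table(attr(passing, "all_pairs"), file.path(outdir, "cerna_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_edge_list(net, file.path(outdir, "cerna_network.sif"))
write.table(cent, file.path(outdir, "centralities.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(top_mirnas, file.path(outdir, "top_mirnas.txt"))

cat(sprintf("universe: %d DE miRNAs; %d candidate pairs, %d passing\n",
            length(universe), nrow(pairs), nrow(passing)))
cat(sprintf("network: %d nodes, %d edges; top-degree lncRNAs: %s\n",
            nrow(net$nodes), nrow(net$edges),
            paste(head(cent$id[order(-cent$degree)], 5), collapse = " ")))
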