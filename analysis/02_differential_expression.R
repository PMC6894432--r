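#!/usr/bin/env Rscript
# Stage 2 — differential expression screening.
#
# TMM normalization, log2-CPM transform, paired per-gene tests; mRNAs
# and lncRNAs pass at FDR < 0.01 and |log2FC| > 1, miRNAs by the
# top/bottom-10 fold-change rule.

suppressMessages(library(cernascreen))

indir <- "results/cohort"; outdir <- "results/de"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

clin <- read_clinical_table(file.path(indir, "clinical.tsv"))
for (role in c("mrna", "lncrna", "mirna")) {
  tag <- c(mrna = "mRNA", lncrna = "lncRNA", mirna = "miRNA")[role]
  counts <- read_expression_matrix(
    file.path(indir, paste0(role, "_counts.tsv")), tag, "counts")
  norm <- to_log2cpm(counts, tmm_factors(counts))
  write_expression_matrix(norm, file.path(outdir, paste0(role, "_log2cpm.tsv")))
  de <- suppressWarnings(paired_de_test(norm, clin))
  de$selected <- if (role == "mirna")
    de$gene_id %in% select_top_bottom_mirnas(de, k = 10)
  else de$gene_id %in% select_de_genes(de, 0.01, 1)
  write.table(de, file.path(outdir, paste0("de_", role, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d genes tested, %d selected\n", tag, nrow(de),
              sum(de$selected)))
}
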