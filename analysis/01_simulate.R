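#!/usr/bin/env Rscript
# Stage 1 — simulate the paired tumor/normal cohort.
#
# Generates the default synthetic cohort (50 tumor/normal pairs; 2,000
# mRNAs, 500 lncRNAs, 150 miRNAs; planted fold changes, five latent
# lncRNA modules with one driven by TNM stage, 80 planted ceRNA pairs
# around 8 hub lncRNAs, 2 of them survival risks) and writes every input
# table the downstream stages consume.

suppressMessages(library(cernascreen))

outdir <- "results/cohort"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = 1)
cohort <- generate_cohort(cfg)

write_expression_matrix(cohort$mrna, file.path(outdir, "mrna_counts.tsv"))
write_expression_matrix(cohort$lncrna, file.path(outdir, "lncrna_counts.tsv"))
write_expression_matrix(cohort$mirna, file.path(outdir, "mirna_counts.tsv"))
write_clinical_table(cohort$clinical, file.path(outdir, "clinical.tsv"))
write_target_edges(cohort$targets, file.path(outdir, "target_edges.tsv"))
truth_report(cohort$truth, file.path(outdir, "ground_truth.tsv"))

cat(sprintf("cohort: %d samples (%d pairs), %d + %d + %d genes\n",
            nrow(cohort$clinical), cfg$n_pairs, nrow(cohort$mrna),
            nrow(cohort$lncrna), nrow(cohort$mirna)))
cat(sprintf("planted: %d DE genes, %d ceRNA pairs, %d candidate hubs, %d modules\n",
            nrow(cohort$truth$de), nrow(cohort$truth$pairs),
            length(cohort$truth$candidates),
            length(unique(cohort$truth$modules$module))))
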