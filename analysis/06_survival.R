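#!/usr/bin/env Rscript
# Stage 6 — Kaplan-Meier survival validation of the candidates.
#
# Median-split of each candidate's tumor expression, two-group log-rank
# test; a candidate is flagged when high expression carries worse
# survival at p < 0.05.

suppressMessages(library(cernascreen))

outdir <- "results/survival"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

clin <- read_clinical_table("results/cohort/clinical.tsv")
expr_lnc <- read_expression_matrix("results/de/lncrna_log2cpm.tsv",
                                   "lncRNA", "log2CPM")
cands <- read.delim("results/select/candidates.tsv")

scr <- survival_screen(cands$lncrna_id, expr_lnc, clin)
write.table(scr, file.path(outdir, "survival_screen.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# per-candidate KM step functions for plotting
km_rows <- do.call(rbind, lapply(cands$lncrna_id, function(id) {
  cl <- clin[clin$condition == "tumor" & !is.na(clin$survival_time), ]
  vals <- tapply(unclass(expr_lnc)[id, cl$sample_id], cl$patient_id, mean)
  surv <- cl[!duplicated(cl$patient_id), ]
  surv <- surv[match(names(vals), surv$patient_id), ]
  labs <- median_split(vals)
  do.call(rbind, lapply(c("high", "low"), function(g) {
    km <- km_estimate(surv$survival_time[labs == g],
                      surv$event[labs == g])
    if (!length(km$time)) return(NULL)
    data.frame(lncrna_id = id, group = g, time = km$time,
               n_risk = km$n_risk, n_event = km$n_event, surv = km$surv)
  }))
}))
write.table(km_rows, file.path(outdir, "km_curves.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d of %d candidates flagged (high expression, worse survival, p < 0.05)\n",
            sum(scr$flagged), nrow(scr)))
print(scr[, c("lncrna_id", "n_high", "n_low", "chi_square", "p",
              "flagged")], row.names = FALSE)
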