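#!/usr/bin/env Rscript
# Similarity among the eight tract-based measures, lesion size and naming:
# one Kendall correlation matrix per tract (pairwise-complete, respecting
# the missing direct metrics of fully disconnected tracts).

suppressPackageStartupMessages(library(clsmverse))

cohort <- suppressWarnings(make_cohort(cohort_spec(seed = 1L)))
p <- cohort$participants
dir.create("results", showWarnings = FALSE)

rows <- list()
for (tn in names(cohort$tracts)) {
  R <- metric_correlations(cohort$metrics, tn, p$lesion_cc, p$naming,
                           method = "kendall")
  ut <- which(upper.tri(R), arr.ind = TRUE)
  rows[[tn]] <- data.frame(tract = tn,
                           a = rownames(R)[ut[, 1]], b = colnames(R)[ut[, 2]],
                           tau = R[upper.tri(R)])
}
tab <- do.call(rbind, rows)
write.table(tab, "results/tract_metric_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# how strongly do direct macro, direct micro and indirect measures agree?
macro_micro <- subset(tab, a %in% c("VOL", "SN") & b %in% c("FA", "MD", "AD", "RD"))
indirect_pairs <- subset(tab, a %in% c("DP", "LP") | b %in% c("DP", "LP"))
cat(sprintf("wrote %d tract-wise correlations\n", nrow(tab)))
cat(sprintf("median |tau| macro-vs-micro: %.2f\n",
            median(abs(macro_micro$tau), na.rm = TRUE)))
cat(sprintf("median |tau| involving indirect measures: %.2f\n",
            median(abs(indirect_pairs$tau), na.rm = TRUE)))
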