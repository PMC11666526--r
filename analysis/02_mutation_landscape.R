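#!/usr/bin/env Rscript
# Per-sample mutation landscape of the simulated cohort: variant-class
# tallies, six-class SNV spectra, top-gene ranking, and the cross-patient
# consistent-gene screen.

suppressPackageStartupMessages(library(neoscreen))

calls <- read_maf("results/cohort/cohort.maf")
foci <- read_cohort("results/cohort/cohort.tsv")$foci
summ <- cohort_summary(calls$variants, foci, interrogated_mb = 38)

dir.create("results/landscape", showWarnings = FALSE, recursive = TRUE)
write_cohort_summary(summ, "results/landscape/sample_summary.tsv",
                     "results/landscape/gene_ranking.tsv")

tal <- summ$class_tally_cohort
cat("Cohort class tallies (non-silent):\n")
for (i in order(-tal$n)) {
  if (tal$n[i] > 0) {
    cat(sprintf("  %-15s %4d  (%.1f%%)\n", tal$variant_class[i], tal$n[i],
                100 * tal$proportion[i]))
  }
}

spect <- snv_six_class_spectrum(calls$variants, by_sample = FALSE)
top2 <- spect[order(-spect$n), ][1:2, ]
cat("Dominant SNV classes:", paste(top2$snv_class, collapse = ", "), "\n")

top <- summ$gene_ranking$ranking
cat("Top 10 genes by samples mutated:",
    paste(utils::head(top$gene, 10), collapse = ", "), "\n")

consist <- consistent_genes_across_patients(calls$variants, foci,
                                            gene_pool = top$gene)
utils::write.table(consist, "results/landscape/consistent_genes.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Genes mutated in every patient with a single class:",
    if (nrow(consist) > 0) paste(consist$gene, collapse = ", ") else "none",
    "\n")
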