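#!/usr/bin/env Rscript
# The neopeptide screen for the multifocal patient: enumerate mutant
# 8-11-mers, apply the 500 nM / mutant-better-than-wild-type filter, rank
# the top 30 with harmonized multi-algorithm scores, and keep candidates
# shared by at least two foci.

suppressPackageStartupMessages(library(neoscreen))

cfg <- sim_config(seed = 4202)
calls <- read_maf("results/cohort/cohort.maf")
foci <- read_cohort("results/cohort/cohort.tsv")$foci
tx <- read_transcript_fasta("results/cohort/transcripts.fa")

# the screen targets the multifocal patient, as the sharing criterion only
# has meaning across that patient's foci
p4 <- foci$sample_id[foci$patient_id == "P4"]
variants <- calls$variants[calls$variants$sample_id %in% p4, ]

pairs <- deduplicate(peptide_pairs(variants, tx))
cat("Candidate pairs after dedup:", nrow(pairs), "from",
    length(unique(pairs$variant_id)), "variants\n")

sb <- simulate_binding(pairs, cfg)
hb <- call_high_binders(pairs, sb$records)
cat("High binders (IC50 mut < 500 nM and < IC50 wt):",
    sum(hb$is_high_binder), "\n")

rk <- select_top(pairs, hb, sb$records, n = 30)
shared <- foci_distribution(rk, min_foci = 2)

dir.create("results/candidates", showWarnings = FALSE, recursive = TRUE)
write_pair_table(pairs, "results/candidates/peptide_pairs.tsv")
write_binder_calls(hb, "results/candidates/binder_calls.tsv")
write_ranking(rk, "results/candidates/top30.tsv")
write_peptide_fasta(rk$table, "results/candidates/top30.fa")
utils::write.table(shared$table, "results/candidates/shared.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("Top 5 by consensus score:\n")
print(utils::head(rk$table[, c("pair_id", "gene", "mt_seq", "ic50_mut",
                               "consensus", "foci")], 5), row.names = FALSE)
cat("Candidates in >= 2 of the", length(p4), "foci:", nrow(shared$table),
    "\n")
if (nrow(shared$table) > 0) {
  cat("  ", paste(unique(shared$table$gene), collapse = ", "), "\n")
}
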