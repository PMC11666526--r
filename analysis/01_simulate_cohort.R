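#!/usr/bin/env Rscript
# Generate the study-sized synthetic cohort every later step analyses:
# 4 patients, the fourth multifocal with two pre-invasive and two invasive
# foci, missense-dominant variant classes, 30% trunk mutations, and a 10%
# per-variant chance of yielding a high-binder neopeptide.

suppressPackageStartupMessages(library(neoscreen))

cfg <- sim_config(seed = 4202)
sim <- simulate_cohort(cfg, dir = "results/cohort")

cat("Simulated cohort written to results/cohort/\n")
cat("  foci:    ", nrow(sim$foci), " across ",
    length(unique(sim$foci$patient_id)), " patients\n", sep = "")
cat("  variants:", nrow(sim$variants), "calls (trunk fraction",
    cfg$trunk_fraction, ")\n")
cat("  genes:   ", length(unique(sim$variants$gene)), "mutated, of",
    cfg$n_genes, "in the toy genome\n")
cat("Files: cohort.maf, transcripts.fa, cohort.tsv, ground_truth.json\n")
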