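#!/usr/bin/env Rscript
# Stage 1 — simulate the study panel.
#
# Generates the control + query variant panel at the study conditions
# (9 benign and 14 pathogenic controls, 54 query VUS), simulates read-class
# counts for every {variant, condition, replicate} sample (>= 7,500 reads,
# 3 replicates, day-2 baseline plus four day-12 arms), and writes per-sample
# allele tables in the ingest dialect so later stages can start from files.

suppressPackageStartupMessages(library(crisprselect))
seed <- 20260925L
dir.create("results", showWarnings = FALSE)

panel <- generate_variant_panel(n_benign_controls = 9, n_pathogenic_controls = 14,
                                n_query = 54, seed = seed)
cfg <- simulation_config(n_reads = 7500, n_replicates = 3, seed = seed)
counts <- simulate_panel(panel, cfg)
edits <- make_edit_definitions(panel, seed = seed)
manifest <- write_allele_tables(counts, edits, "results/allele_tables")
write.table(panel, "results/panel.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Simulated %d variants (%d samples of %d reads) -> %d allele tables\n",
            nrow(panel), nrow(counts), cfg$n_reads, nrow(manifest)))
cat("Role composition:\n")
print(table(panel$role))
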