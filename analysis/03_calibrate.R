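#!/usr/bin/env Rscript
# Stage 3 — calibrate the assay from its control variants.
#
# Scores each control by its worst-case (minimum) day-12 replicate-mean
# normalized ratio, builds the ROC over the 14 pathogenic + 9 benign
# controls, estimates sensitivity/specificity with Wilson 95% CIs at the
# 25% / 50% thresholds, computes the OddsPath pair (with the pure-class
# correction for a perfect binary readout), and maps it to the PS3/BS3
# evidence strength used downstream.

suppressPackageStartupMessages(library(crisprselect))

panel <- read.delim("results/panel.tsv")
summary_df <- read.delim("results/ratio_summary.tsv")
scores <- calibration_scores(summary_df)

truth_map <- c(control_benign = "benign", control_pathogenic = "pathogenic")
controls <- merge(panel[panel$role %in% names(truth_map),
                        c("variant_id", "role")], scores, by = "variant_id")
controls$truth <- unname(truth_map[controls$role])

cal <- calibrate_assay(controls, threshold_deleterious = 25,
                       threshold_neutral = 50, confidence = 0.95)
print(cal)

jsonlite::write_json(unclass(cal), "results/calibration.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Calibration written to results/calibration.json\n")
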