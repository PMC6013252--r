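#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Generates the default synthetic cohort: six interaction databases in two
# identifier namespaces, a localization table with whitelist, five paired
# (two-normalization) expression datasets with drug-masked disease
# samples, a signaling spec, a drug-target list, and the ground truth.
# Everything downstream reads the files written here.

suppressPackageStartupMessages(library(cppinet))

seed <- 1L
cohort_dir <- "results/cohort"

fx <- generate_fixture(synthetic_config(seed = seed))
paths <- write_fixture(fx, cohort_dir)

cat("Synthetic cohort written to", cohort_dir, "\n")
cat("  sources:          ", length(fx$sources), "\n")
cat("  records/source:   ",
    paste(fx$truth$per_source_emitted, collapse = ", "), "\n")
cat("  expression sets:  ", length(fx$datasets),
    "(two normalization variants each)\n")
cat("  planted key genes:",
    paste(fx$truth$planted_key_genes, collapse = ", "), "\n")
cat("  planted co-expressed edges:",
    nrow(fx$truth$planted_coexpressed_edges), "\n")
cat("  drug-masked samples:",
    sum(lengths(fx$truth$masked_samples)), "\n")
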