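#!/usr/bin/env Rscript
# Stage 2 — merge interaction sources and derive the tissue-specific
# interactome.
#
# Maps every source to gene-symbol space (dropping and counting
# unmappable records), merges into one non-redundant edge set with
# provenance, then applies the two tissue filters: plasma-membrane /
# cytoplasm localization (with the receptor/TF whitelist) and
# disease-sample co-expression (Pearson r > 0.7 in at least one dataset,
# RMA-standing normalization variant).

suppressPackageStartupMessages(library(cppinet))

fx <- read_fixture("results/cohort")

mapped <- lapply(fx$sources, function(s)
  map_to_gene_symbols(s, fx$id_map)$records)
unmapped <- vapply(fx$sources, function(s)
  sum(map_to_gene_symbols(s, fx$id_map)$unmapped), 0L)
ppi <- merge_interactions(mapped)
write_unified_ppi(ppi, "results/merged_ppi.tsv")

loc <- localization_filter(ppi, fx$localization)
coex <- coexpression_filter(loc$ppi, lapply(fx$datasets, `[[`, "A"),
                            coexpression_config())
write_unified_ppi(coex$ppi, "results/sppin_edges.tsv")
write.table(coex$r_table, "results/coexpression_r.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Merged interactome:", nrow(ppi$edges), "non-redundant edges from",
    ppi$n_records_in, "records;", ppi$n_self_loops, "self-loops removed\n")
cat("Unmappable records per source:",
    paste(names(unmapped), unmapped, sep = "=", collapse = ", "), "\n")
cat("After localization filter:", nrow(loc$ppi$edges), "edges over",
    length(loc$g_list), "genes (the G-list)\n")
cat("After co-expression filter (SPPIN):", nrow(coex$ppi$edges),
    "edges\n")
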