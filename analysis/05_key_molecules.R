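#!/usr/bin/env Rscript
# Stage 5 — select key molecules, classify pathway directionality, and
# run the therapy-effect analysis.
#
# Key molecules: genes in the top sets of >= 3 centrality measures and DE
# in >= 3 datasets, OR >= 2 measures and >= 4 datasets. Samples of each
# dataset are hierarchically clustered (1 - Pearson, average linkage) on
# key-gene expression; disease samples co-clustering with controls are
# treated as therapy-masked, removed, and the selection repeated.

suppressPackageStartupMessages(library(cppinet))

fx <- read_fixture("results/cohort")
cppin_edges <- read.delim("results/cppin_edges.tsv")
sppin <- build_graph(read_unified_ppi("results/sppin_edges.tsv")$edges)
cppin <- build_cppin(sppin, fx$spec)
cent <- read.delim("results/centrality.tsv")
de_table <- read.delim("results/de_calls.tsv")

membership <- stats::setNames(cent$n_measures, cent$node)
prof <- de_profile(de_table)
sel <- select_key_molecules(membership, prof$counts)
write.table(sel$report[order(-sel$report$n_measures,
                             -sel$report$n_de_datasets), ],
            "results/key_molecule_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

consensus <- consensus_direction(prof$directions)
directionality <- classify_path_directionality(cppin$path_sets,
                                               cppin$pair_table, consensus)
write.table(directionality, "results/path_directionality.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cluster_rows <- list()
misclustered <- list()
for (dp in fx$datasets) {
  cl <- cluster_samples(dp$A, sel$keys)
  misclustered[[dp$name]] <- cl$misclustered
  cluster_rows[[dp$name]] <- data.frame(
    dataset = dp$name, sample = names(cl$labels),
    cluster = unname(cl$labels),
    group = unname(dp$A$groups[names(cl$labels)]))
}
write.table(do.call(rbind, cluster_rows), "results/sample_clusters.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

rerun <- remove_and_rerun(fx$datasets, misclustered, membership, sel$keys)
write.table(data.frame(gene = c(rerun$retained, rerun$additional),
                       status = rep(c("retained", "additional"),
                                    c(length(rerun$retained),
                                      length(rerun$additional)))),
            "results/therapy_rerun.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Key molecules:", length(sel$keys), "->",
    paste(sel$keys, collapse = ", "), "\n")
cat("Pathway directionality labels:\n")
print(table(directionality$label))
cat("Disease samples co-clustering with controls:",
    sum(lengths(misclustered)), "\n")
cat("After removal:", length(rerun$retained), "retained +",
    length(rerun$additional), "additional (",
    paste(rerun$additional, collapse = ", "), ")\n")
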