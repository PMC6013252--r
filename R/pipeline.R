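#' Run the full key-molecule discovery pipeline on a fixture
#'
#' Executes every stage in order: identifier mapping and source merging,
#' localization filtering, disease-sample co-expression filtering, SPPIN
#' construction, shortest-path CPPIN assembly, centrality scoring and
#' top-fraction extraction, dual-normalization differential-expression
#' calling, key-molecule selection, per-dataset sample clustering with
#' drug-masked-sample detection, the remove-and-rerun therapy analysis,
#' and (optionally) the Monte-Carlo drug-target overlap test.
#'
#' @param fixture a `synthetic_fixture` (or any list with the same
#'   `sources`/`id_map`/`localization`/`datasets`/`spec`/`drug_targets`
#'   components).
#' @param fraction top-centrality fraction; default 0.20.
#' @param coexpr_cfg `coexpression_config`.
#' @param de_cfg `de_config`.
#' @param rule `selection_rule`.
#' @param cluster_cfg `clustering_config`.
#' @param overlap_samples Monte-Carlo draws for the drug-target test; 0
#'   skips the resampling stage.
#' @param overlap_seed seed for the resampler.
#' @return A `cppin_pipeline` list with all stage outputs: `ppi`,
#'   `unmapped`, `sppin_edges`, `g_list`, `sppin`, `cppin` (a
#'   `cppin_result`), `centrality`, `top`, `de_table`, `profile`,
#'   `selection`, `keys`, `clustering` (per dataset), `misclustered`,
#'   `rerun`, `overlap`, `null` (when sampled).
#' @export
run_cppin_pipeline <- function(fixture,
                               fraction = 0.20,
                               coexpr_cfg = coexpression_config(),
                               de_cfg = de_config(),
                               rule = selection_rule(),
                               cluster_cfg = clustering_config(),
                               overlap_samples = 0,
                               overlap_seed = 1L) {
  mapped <- list()
  unmapped <- integer()
  for (src in fixture$sources) {
    m <- map_to_gene_symbols(src, fixture$id_map)
    mapped[[length(mapped) + 1L]] <- m$records
    unmapped <- c(unmapped, m$unmapped)
  }
  ppi <- merge_interactions(mapped)
  locf <- localization_filter(ppi, fixture$localization)
  coex <- coexpression_filter(locf$ppi, lapply(fixture$datasets, `[[`, "A"),
                              coexpr_cfg)
  sppin <- build_graph(coex$ppi$edges)
  cppin <- build_cppin(sppin, fixture$spec)
  cent <- centrality_table(cppin$graph)
  top <- top_fraction(cent, fraction)
  candidates <- top$union
  de_table <- run_diffexpr(fixture$datasets, candidates, de_cfg)
  prof <- de_profile(de_table)
  sel <- select_key_molecules(top$membership, prof$counts, rule)
  clustering <- lapply(fixture$datasets, function(dp)
    tryCatch(cluster_samples(dp$A, sel$keys, cluster_cfg),
             error = function(e) NULL))
  names(clustering) <- vapply(fixture$datasets, `[[`, "", "name")
  misclustered <- lapply(clustering, function(cl)
    if (is.null(cl)) character() else cl$misclustered)
  rerun <- if (any(lengths(misclustered) > 0L))
    remove_and_rerun(fixture$datasets, misclustered, top$membership,
                     sel$keys, rule, de_cfg)
  else list(keys = sel$keys, retained = sel$keys,
            additional = character(), de_table = de_table)
  consensus <- consensus_direction(prof$directions)
  directionality <- classify_path_directionality(cppin$path_sets,
                                                 cppin$pair_table, consensus)
  overlap <- NULL
  null <- NULL
  if (length(sel$keys) > 0L && length(fixture$drug_targets) > 0L) {
    keys_in <- intersect(sel$keys, igraph::V(cppin$graph)$name)
    overlap <- observed_stats(cppin$graph, keys_in, fixture$drug_targets)
    if (overlap_samples > 0) {
      null <- resample_null(cppin$graph, length(keys_in),
                            fixture$drug_targets, overlap$n_overlap,
                            overlap$n_direct, overlap_samples, overlap_seed)
    }
  }
  structure(list(ppi = ppi, unmapped = unmapped,
                 g_list = locf$g_list,
                 sppin_edges = coex$ppi$edges, sppin = sppin,
                 cppin = cppin, centrality = cent, top = top,
                 de_table = de_table, profile = prof,
                 selection = sel, keys = sel$keys,
                 directionality = directionality,
                 clustering = clustering, misclustered = misclustered,
                 rerun = rerun, overlap = overlap, null = null),
            class = "cppin_pipeline")
}

#' @export
print.cppin_pipeline <- function(x, ...) {
  cat("CPPIN pipeline run\n")
  cat("  merged PPI edges:  ", nrow(x$ppi$edges), "\n")
  cat("  SPPIN edges:       ", nrow(x$sppin_edges), "\n")
  cat("  CPPIN:             ", igraph::vcount(x$cppin$graph), "nodes /",
      igraph::ecount(x$cppin$graph), "edges\n")
  cat("  central nodes:     ", length(x$top$union), "\n")
  cat("  key molecules:     ", length(x$keys), "\n")
  if (!is.null(x$overlap))
    cat("  drug-target overlap:", x$overlap$n_overlap, "| direct links:",
        x$overlap$n_direct, "\n")
  invisible(x)
}

#' Precision and recall of a recovered set against a planted set
#'
#' @param recovered,planted character vectors.
#' @return list with `precision`, `recall` (both 1 when `recovered` and
#'   `planted` are both empty).
#' @export
set_precision_recall <- function(recovered, planted) {
  tp <- length(intersect(recovered, planted))
  precision <- if (length(recovered) == 0L) 1 else tp / length(recovered)
  recall <- if (length(planted) == 0L) 1 else tp / length(planted)
  list(precision = precision, recall = recall)
}
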