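#' Key-molecule selection rule
#'
#' An OR of clauses, each requiring membership in at least
#' `min_centrality_measures` of the four top-centrality sets and
#' differential expression in at least `min_de_datasets` datasets. The
#' default is the two-clause rule (>=3 measures and >=3 datasets) OR
#' (>=2 measures and >=4 datasets).
#'
#' @param clauses list of 2-element integer vectors
#'   c(min_centrality_measures, min_de_datasets).
#' @return a `selection_rule` list.
#' @export
selection_rule <- function(clauses = list(c(3L, 3L), c(2L, 4L))) {
  for (cl in clauses)
    if (length(cl) != 2L || any(cl < 1L))
      stop("each clause is c(min_measures, min_datasets), both positive")
  structure(list(clauses = clauses), class = "selection_rule")
}

#' Select key molecules
#'
#' A gene is a key molecule iff some clause of the rule is satisfied by
#' its centrality membership count and DE dataset count.
#'
#' @param membership named integer vector gene -> number of centrality
#'   measures (0..4) in whose top set the gene appears.
#' @param de_counts named integer vector gene -> number of datasets in
#'   which the gene is differentially expressed.
#' @param rule `selection_rule`.
#' @return list with `keys` (sorted key gene symbols) and `report`
#'   (data.frame: gene, n_measures, n_de_datasets, clause fired or NA).
#' @export
select_key_molecules <- function(membership, de_counts,
                                 rule = selection_rule()) {
  genes <- names(membership)
  de <- stats::setNames(integer(length(genes)), genes)
  common <- intersect(genes, names(de_counts))
  de[common] <- de_counts[common]
  clause_fired <- rep(NA_integer_, length(genes))
  for (i in seq_along(rule$clauses)) {
    cl <- rule$clauses[[i]]
    hit <- membership >= cl[1L] & de >= cl[2L] & is.na(clause_fired)
    clause_fired[hit] <- i
  }
  report <- data.frame(gene = genes,
                       n_measures = unname(membership),
                       n_de_datasets = unname(de),
                       clause = clause_fired,
                       stringsAsFactors = FALSE)
  list(keys = sort(genes[!is.na(clause_fired)]), report = report)
}

#' Classify differential-expression directionality along shortest paths
#'
#' For each cytokine/transcription-factor pairing, counts up- and
#' down-regulated molecules (by per-molecule consensus direction) over the
#' union of its shortest-path molecules (receptor genes, intermediates and
#' TF subunit genes) and labels the pathway.
#'
#' @param path_sets named list of `path_set` objects keyed by
#'   "receptor\\rtf_gene" as produced by [build_cppin()].
#' @param pair_table pair table from [build_cppin()] (one row per
#'   receptor x subunit combination with `cytokine` and `tf_name`).
#' @param consensus named character vector gene -> "up"/"down"/"none"
#'   (see [consensus_direction()]).
#' @return data.frame: `cytokine`, `tf_name`, `n_molecules`, `n_up`,
#'   `n_down`, `label` in {exclusively_up, mostly_up, mixed, mostly_down,
#'   exclusively_down, no_de}.
#' @export
classify_path_directionality <- function(path_sets, pair_table, consensus) {
  key <- paste(pair_table$receptor, pair_table$tf_gene, sep = "\r")
  grp <- paste(pair_table$cytokine, pair_table$tf_name, sep = "\r")
  out <- lapply(split(seq_len(nrow(pair_table)), grp), function(idx) {
    mols <- unique(unlist(lapply(key[idx], function(k) {
      ps <- path_sets[[k]]
      if (is.null(ps)) character() else unlist(ps$paths)
    })))
    dirs <- consensus[intersect(mols, names(consensus))]
    n_up <- sum(dirs == "up"); n_dn <- sum(dirs == "down")
    label <- if (n_up == 0 && n_dn == 0) "no_de"
    else if (n_dn == 0) "exclusively_up"
    else if (n_up == 0) "exclusively_down"
    else if (n_up > n_dn) "mostly_up"
    else if (n_dn > n_up) "mostly_down"
    else "mixed"
    data.frame(cytokine = pair_table$cytokine[idx[1L]],
               tf_name = pair_table$tf_name[idx[1L]],
               n_molecules = length(mols), n_up = n_up, n_down = n_dn,
               label = label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$cytokine, out$tf_name), , drop = FALSE]
}

#' Clustering configuration for therapy-effect analysis
#'
#' @param distance "one_minus_pearson" (default) or "euclidean" between
#'   sample expression profiles.
#' @param linkage agglomeration method: "average" (default), "complete"
#'   or "ward" (ward.D2).
#' @param k number of clusters at the cut; default 2 (disease vs control).
#' @return a `clustering_config` list.
#' @export
clustering_config <- function(distance = c("one_minus_pearson", "euclidean"),
                              linkage = c("average", "complete", "ward"),
                              k = 2L) {
  if (k < 2L) stop("k must be >= 2")
  structure(list(distance = match.arg(distance),
                 linkage = match.arg(linkage), k = as.integer(k)),
            class = "clustering_config")
}

#' Hierarchically cluster samples on key-gene expression
#'
#' Agglomerative clustering of the samples of one dataset restricted to
#' the key genes; reports per-cluster disease/control composition and the
#' disease samples that co-cluster with a majority-control cluster
#' ("misclustered" — the drug-effect signature).
#'
#' @param dataset `expression_dataset`.
#' @param key_genes genes to cluster on (>= 2 must be measured).
#' @param cfg `clustering_config`.
#' @return list with `labels` (named integer cluster per sample), `tree`
#'   (hclust object), `composition` (cluster x group table) and
#'   `misclustered` (disease sample ids in majority-control clusters).
#' @export
cluster_samples <- function(dataset, key_genes, cfg = clustering_config()) {
  genes <- intersect(norm_symbol(key_genes), rownames(dataset$matrix))
  if (length(genes) < 2L) stop("need >= 2 measured key genes")
  mat <- dataset$matrix[genes, , drop = FALSE]
  if (ncol(mat) < 2L) stop("need >= 2 samples")
  d <- switch(cfg$distance,
    one_minus_pearson = {
      r <- suppressWarnings(stats::cor(mat))
      r[is.na(r)] <- 0     # zero-variance samples: maximally distant
      stats::as.dist(1 - r)
    },
    euclidean = stats::dist(t(mat)))
  method <- if (cfg$linkage == "ward") "ward.D2" else cfg$linkage
  tree <- stats::hclust(d, method = method)
  labels <- stats::cutree(tree, k = min(cfg$k, ncol(mat)))
  composition <- table(cluster = labels, group = dataset$groups[names(labels)])
  maj_control <- rownames(composition)[composition[, "control"] >
                                         composition[, "disease"]]
  mis <- names(labels)[as.character(labels) %in% maj_control &
                         dataset$groups[names(labels)] == "disease"]
  list(labels = labels, tree = tree, composition = composition,
       misclustered = mis)
}

#' Repeat selection after removing drug-masked disease samples
#'
#' Removes the given disease samples from their datasets, recomputes
#' differential expression for the centrality-selected genes, re-applies
#' the identical selection rule, and partitions the result into retained
#' (previously key) and newly selected genes. A dataset left with fewer
#' than 2 disease samples is dropped from the counts with a warning.
#'
#' @param dataset_pairs list as in [run_diffexpr()].
#' @param remove named list dataset name -> disease sample ids to remove
#'   (or a character vector applied to every dataset).
#' @param membership centrality membership counts (see
#'   [select_key_molecules()]).
#' @param previous_keys key set from the original selection.
#' @param rule `selection_rule`.
#' @param cfg `de_config`.
#' @return list with `keys`, `retained`, `additional`, `de_table`.
#' @export
remove_and_rerun <- function(dataset_pairs, remove, membership,
                             previous_keys, rule = selection_rule(),
                             cfg = de_config()) {
  drop_samples <- function(ds, ids) {
    keep <- setdiff(colnames(ds$matrix), ids)
    ds$matrix <- ds$matrix[, keep, drop = FALSE]
    ds$groups <- ds$groups[keep]
    ds
  }
  reduced <- list()
  for (dp in dataset_pairs) {
    ids <- if (is.list(remove)) remove[[dp$name]] %||% character() else remove
    dp$A <- drop_samples(dp$A, ids)
    dp$B <- drop_samples(dp$B, ids)
    if (sum(dp$A$groups == "disease") < 2L) {
      warning("dataset ", dp$name,
              " left with < 2 disease samples; dropped from DE counts")
      next
    }
    reduced[[length(reduced) + 1L]] <- dp
  }
  de_table <- run_diffexpr(reduced, names(membership), cfg)
  prof <- de_profile(de_table)
  sel <- select_key_molecules(membership, prof$counts, rule)
  list(keys = sel$keys,
       retained = intersect(sel$keys, previous_keys),
       additional = setdiff(sel$keys, previous_keys),
       de_table = de_table)
}
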