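#' Build a simple undirected gene graph
#'
#' Nodes are uppercase gene symbols; parallel edges and self-loops are
#' dropped so that shortest-path and centrality semantics are those of a
#' simple graph.
#'
#' @param edges data.frame with the first two columns holding endpoint
#'   symbols (e.g. the `edges` of a `unified_ppi`), or a 2-column matrix.
#' @param isolated optional extra node names to include without edges.
#' @return an igraph undirected simple graph with vertex names.
#' @export
build_graph <- function(edges, isolated = character()) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  a <- norm_symbol(as.character(edges[[1L]]))
  b <- norm_symbol(as.character(edges[[2L]]))
  keep <- a != b
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = unique(c(a, b, norm_symbol(isolated))))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Enumerate all shortest paths between two genes
#'
#' Breadth-first search with full predecessor sets: every geodesic between
#' `source` and `target` is returned. Unreachable pairs give an empty path
#' list with `length = Inf` (the unreachable marker); `source == target`
#' gives a single zero-length path.
#'
#' @param graph igraph graph from [build_graph()].
#' @param source,target vertex names.
#' @return A `path_set` list: `source`, `target`, `length`, `paths` (list
#'   of character vectors, each a node sequence from source to target).
#' @export
all_shortest_paths <- function(graph, source, target) {
  vn <- igraph::V(graph)$name
  if (!(source %in% vn)) stop("node not in graph: ", source)
  if (!(target %in% vn)) stop("node not in graph: ", target)
  if (source == target) {
    return(structure(list(source = source, target = target, length = 0L,
                          paths = list(source)), class = "path_set"))
  }
  res <- igraph::all_shortest_paths(graph, from = source, to = target,
                                    mode = "all")
  paths <- lapply(res$res, function(p) igraph::V(graph)$name[as.integer(p)])
  if (length(paths) == 0L) {
    return(structure(list(source = source, target = target, length = Inf,
                          paths = list()), class = "path_set"))
  }
  structure(list(source = source, target = target,
                 length = length(paths[[1L]]) - 1L, paths = paths),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("%s -> %s: %d geodesic(s) of length %s\n", x$source, x$target,
              length(x$paths), format(x$length)))
  invisible(x)
}

#' Expand a signaling spec into receptor-gene x TF-subunit-gene pairs
#'
#' For each cytokine/transcription-factor row, emits every (receptor gene,
#' TF subunit gene) combination; the per-row combination count is
#' |receptors| x |subunits| and their grand total is the number of
#' source-target shortest-path routes the network analysis considers.
#'
#' @param spec signaling-spec data.frame (see [signaling_spec_rasf()]).
#' @return list with `pairs` (data.frame: row index, cytokine, tf_name,
#'   receptor, tf_gene), `row_counts` (per-row combination count) and
#'   `total`.
#' @export
enumerate_receptor_tf_pairs <- function(spec) {
  recs <- split_genes(spec$receptors)
  subs <- split_genes(spec$tf_genes)
  row_counts <- lengths(recs) * lengths(subs)
  pairs <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    expand.grid(row = i, cytokine = spec$cytokine[i],
                tf_name = spec$tf_name[i],
                receptor = recs[[i]], tf_gene = subs[[i]],
                stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, row_counts = row_counts, total = sum(row_counts))
}

#' Collect shortest-path intermediates
#'
#' Interior nodes of the supplied geodesics, minus every receptor gene and
#' TF subunit gene of the signaling spec. The occurrence count of an
#' intermediate is the number of geodesics that contain it.
#'
#' @param path_sets list of `path_set` objects.
#' @param spec signaling-spec data.frame.
#' @return list with `intermediates` (sorted character vector) and
#'   `occurrence` (named integer vector over intermediates).
#' @export
extract_intermediates <- function(path_sets, spec) {
  endpoints <- unique(c(unlist(split_genes(spec$receptors)),
                        unlist(split_genes(spec$tf_genes)),
                        norm_symbol(spec$cytokine)))
  tally <- new.env(parent = emptyenv())
  for (ps in path_sets) {
    for (p in ps$paths) {
      if (length(p) < 3L) next
      interior <- setdiff(unique(p[-c(1L, length(p))]), endpoints)
      for (v in interior)
        assign(v, (get0(v, envir = tally, ifnotfound = 0L)) + 1L,
               envir = tally)
    }
  }
  inter <- sort(ls(tally))
  occ <- vapply(inter, get, integer(1L), envir = tally)
  list(intermediates = inter, occurrence = occ)
}

#' Distance-1 neighborhood of a seed set
#'
#' Union of the adjacency sets of all seeds. A seed appears in the result
#' only if it is itself adjacent to another seed.
#'
#' @param graph igraph graph.
#' @param seeds vertex names (must be in the graph).
#' @return character vector of neighbor names.
#' @export
neighborhood_nodes <- function(graph, seeds) {
  vn <- igraph::V(graph)$name
  bad <- setdiff(seeds, vn)
  if (length(bad)) stop("seeds not in graph: ", paste(bad, collapse = ", "))
  if (length(seeds) == 0L) return(character())
  nb <- igraph::adjacent_vertices(graph, seeds)
  sort(unique(unlist(lapply(nb, function(v) vn[as.integer(v)]))))
}

#' Assemble the cytokine PPI network (CPPIN)
#'
#' Node set: cytokine nodes, the spec's receptor genes and TF subunit
#' genes present in the source network, the shortest-path intermediates
#' and the intermediates' distance-1 neighbors. Edge set: the
#' source-network-induced subgraph on those nodes, plus one explicit
#' cytokine-receptor edge per (cytokine, receptor gene) pair of the spec.
#' Cytokine node labels may coincide with gene symbols; collisions are
#' resolved by role-tagging, never renaming.
#'
#' @param sppin igraph graph (the tissue-specific network).
#' @param spec signaling-spec data.frame.
#' @param intermediates character vector of intermediate genes.
#' @param neighbors character vector of neighborhood genes.
#' @param induced if FALSE, only edges incident to an intermediate (seed)
#'   or a spec gene are retained rather than the full induced subgraph.
#' @return A `cppin_result` list: `graph` (igraph), `node_roles` (named
#'   list node -> character vector of roles), `skip_report` (spec genes
#'   absent from the source network).
#' @export
assemble_cppin <- function(sppin, spec, intermediates, neighbors,
                           induced = TRUE) {
  vn <- igraph::V(sppin)$name
  cytokines <- unique(norm_symbol(spec$cytokine))
  receptors <- unique(unlist(split_genes(spec$receptors)))
  tf_genes <- unique(unlist(split_genes(spec$tf_genes)))
  skip <- setdiff(c(receptors, tf_genes), vn)
  gene_nodes <- unique(c(intersect(c(receptors, tf_genes), vn),
                         intermediates, neighbors))
  sub <- igraph::induced_subgraph(sppin, gene_nodes)
  if (!induced) {
    core <- unique(c(intersect(c(receptors, tf_genes), vn), intermediates))
    el <- igraph::as_edgelist(sub)
    keep <- el[, 1L] %in% core | el[, 2L] %in% core
    sub <- igraph::subgraph_from_edges(
      sub, igraph::E(sub)[keep], delete.vertices = FALSE)
  }
  # explicit cytokine -> receptor edges; cytokine vertices added as needed
  cyt_edges <- unique(do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    rg <- intersect(split_genes(spec$receptors[i])[[1L]], gene_nodes)
    if (length(rg) == 0L) return(NULL)
    cbind(norm_symbol(spec$cytokine[i]), rg)
  })))
  g <- sub
  if (!is.null(cyt_edges)) {
    new_v <- setdiff(cyt_edges[, 1L], igraph::V(g)$name)
    if (length(new_v)) g <- igraph::add_vertices(g, length(new_v),
                                                 name = new_v)
    idx <- rbind(match(cyt_edges[, 1L], igraph::V(g)$name),
                 match(cyt_edges[, 2L], igraph::V(g)$name))
    g <- igraph::add_edges(g, as.vector(idx))
    g <- igraph::simplify(g)
  }
  roles <- stats::setNames(vector("list", igraph::vcount(g)),
                           igraph::V(g)$name)
  add_role <- function(nodes, role) {
    for (v in intersect(nodes, names(roles)))
      roles[[v]] <<- union(roles[[v]], role)
  }
  add_role(cytokines, "cytokine")
  add_role(receptors, "receptor")
  add_role(tf_genes, "tf")
  add_role(intermediates, "intermediate")
  add_role(neighbors, "neighbor")
  for (v in names(roles)) if (is.null(roles[[v]])) roles[[v]] <- "neighbor"
  structure(list(graph = g, node_roles = roles, skip_report = skip),
            class = "cppin_result")
}

#' @export
print.cppin_result <- function(x, ...) {
  cat("CPPIN:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges;",
      length(x$skip_report), "spec gene(s) absent from source network\n")
  invisible(x)
}

#' Run the full shortest-path network construction
#'
#' Enumerates receptor/TF-subunit pairs from the spec, extracts all
#' shortest paths for each pair present and connected in the source
#' network, collects intermediates and their neighborhoods, and assembles
#' the CPPIN.
#'
#' @param sppin igraph tissue-specific network.
#' @param spec signaling-spec data.frame.
#' @param induced passed to [assemble_cppin()].
#' @return A `cppin_result` augmented with `path_sets`, `pair_table`
#'   (per-pair geodesic length and count; unreachable/absent pairs
#'   flagged), `combination_counts` (per spec row) and
#'   `intermediate_occurrence`.
#' @export
build_cppin <- function(sppin, spec, induced = TRUE) {
  vn <- igraph::V(sppin)$name
  enum <- enumerate_receptor_tf_pairs(spec)
  prs <- enum$pairs
  # one BFS per distinct (receptor, tf_gene) pair; rows share results
  key <- paste(prs$receptor, prs$tf_gene, sep = "\r")
  uniq <- !duplicated(key)
  path_sets <- list()
  status <- character(nrow(prs))
  for (i in which(uniq)) {
    r <- prs$receptor[i]; t <- prs$tf_gene[i]
    if (!(r %in% vn) || !(t %in% vn)) {
      path_sets[[key[i]]] <- NULL
      next
    }
    path_sets[[key[i]]] <- all_shortest_paths(sppin, r, t)
  }
  stat_of <- function(k) {
    ps <- path_sets[[k]]
    if (is.null(ps)) c(NA_real_, 0)
    else c(ps$length, length(ps$paths))
  }
  st <- vapply(key, stat_of, numeric(2L))
  prs$geodesic_length <- st[1L, ]
  prs$n_geodesics <- st[2L, ]
  prs$status <- ifelse(is.na(prs$geodesic_length), "absent",
                       ifelse(is.infinite(prs$geodesic_length),
                              "unreachable", "connected"))
  inter <- extract_intermediates(path_sets, spec)
  nbrs <- neighborhood_nodes(sppin, inter$intermediates)
  res <- assemble_cppin(sppin, spec, inter$intermediates, nbrs,
                        induced = induced)
  res$path_sets <- path_sets
  res$pair_table <- prs
  res$combination_counts <- enum$row_counts
  res$intermediate_occurrence <- inter$occurrence
  res$neighbors <- nbrs
  res
}
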