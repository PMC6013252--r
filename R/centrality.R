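#' Degree centrality
#'
#' Fraction of the other n-1 nodes a node is directly connected to:
#' deg(v)/(n-1).
#'
#' @param graph igraph simple undirected graph with >= 2 nodes.
#' @return named numeric vector in [0, 1].
#' @export
degree_centrality <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2L) stop("degree centrality needs at least 2 nodes")
  d <- igraph::degree(graph, mode = "all", loops = FALSE)
  d / (n - 1)
}

#' Betweenness centrality
#'
#' Unnormalized betweenness: for each unordered pair {s, t} with both
#' different from v, the fraction of s-t geodesics passing through v,
#' summed over pairs. Disconnected pairs contribute 0; endpoints are
#' excluded. No rescaling by 2/((n-1)(n-2)) is applied — downstream use is
#' rank-based.
#'
#' @param graph igraph graph.
#' @return named numeric vector >= 0.
#' @export
betweenness_centrality <- function(graph) {
  igraph::betweenness(graph, directed = FALSE, normalized = FALSE)
}

#' Closeness centrality
#'
#' Reciprocal of the summed geodesic distances from a node to every other
#' node. On disconnected graphs the sum runs within the node's connected
#' component (unreachable pairs are undefined under the plain definition);
#' an isolated node scores 0. A harmonic variant (sum of reciprocal
#' distances, defined across components) is available via `mode`.
#'
#' @param graph igraph graph.
#' @param mode "component" (default) or "harmonic".
#' @return named numeric vector.
#' @export
closeness_centrality <- function(graph, mode = c("component", "harmonic")) {
  mode <- match.arg(mode)
  d <- igraph::distances(graph)
  diag(d) <- NA
  if (mode == "harmonic") {
    h <- 1 / d
    h[is.infinite(d)] <- 0
    return(rowSums(h, na.rm = TRUE))
  }
  d[is.infinite(d)] <- NA
  s <- rowSums(d, na.rm = TRUE)
  out <- ifelse(s > 0, 1 / s, 0)
  stats::setNames(out, igraph::V(graph)$name)
}

#' Eigenvector centrality
#'
#' Entries of the principal eigenvector of the adjacency matrix, computed
#' by power iteration, sign-fixed nonnegative (Perron-Frobenius) and
#' rescaled so the maximum entry is 1. On disconnected graphs the scores
#' are dominated by the component with the largest spectral radius; other
#' components receive (numerically) zero scores.
#'
#' @param graph non-empty igraph graph.
#' @param tol convergence threshold on the L1 change between successive
#'   normalized iterates.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return named numeric vector in [0, 1] with max 1.
#' @export
eigenvector_centrality <- function(graph, tol = 1e-10, max_iter = 10000L) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  if (igraph::ecount(graph) == 0L)
    return(stats::setNames(rep(0, n), igraph::V(graph)$name))
  x <- rep(1 / n, n)
  # shifted iteration (A + I) keeps the eigenvectors of A but breaks the
  # +/- lambda oscillation of bipartite components
  for (i in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x
    s <- sum(abs(y))
    if (s == 0) break
    y <- y / s
    if (sum(abs(y - x)) < tol) {
      x <- y
      x[x < 0] <- 0
      return(stats::setNames(x / max(x), igraph::V(graph)$name))
    }
    x <- y
  }
  stop("eigenvector centrality failed to converge after ", max_iter,
       " iterations on graph with ", n, " nodes")
}

#' Compute the four-centrality table
#'
#' @param graph igraph graph.
#' @return data.frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`, `eigenvector`.
#' @export
centrality_table <- function(graph) {
  data.frame(node = igraph::V(graph)$name,
             degree = unname(degree_centrality(graph)),
             betweenness = unname(betweenness_centrality(graph)),
             closeness = unname(closeness_centrality(graph)),
             eigenvector = unname(eigenvector_centrality(graph)),
             stringsAsFactors = FALSE)
}

#' Extract the top fraction of nodes per centrality measure
#'
#' Per measure, the ceiling(fraction * n) highest-scoring nodes are
#' selected; with the default tie policy the whole tie block straddling
#' the cut is included ("approximately" the fraction), with
#' `"strict_count"` exactly ceiling(fraction * n) nodes are taken in
#' score order (ties broken by node name for determinism).
#'
#' @param table data.frame from [centrality_table()].
#' @param fraction fraction in (0, 1]; default 0.20.
#' @param tie_policy "include_ties" (default) or "strict_count".
#' @return list with `per_measure` (named list of node sets), `membership`
#'   (named integer vector node -> number of measures selected in, 0..4)
#'   and `union` (nodes selected in >= 1 measure).
#' @export
top_fraction <- function(table, fraction = 0.20,
                         tie_policy = c("include_ties", "strict_count")) {
  tie_policy <- match.arg(tie_policy)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (nrow(table) == 0L) stop("empty centrality table")
  k <- ceiling(fraction * nrow(table))
  measures <- c("degree", "betweenness", "closeness", "eigenvector")
  per <- lapply(measures, function(m) {
    sc <- table[[m]]
    ord <- order(-sc, table$node)
    if (tie_policy == "include_ties") {
      cutoff <- sc[ord[k]]
      table$node[sc >= cutoff]
    } else {
      table$node[ord[seq_len(k)]]
    }
  })
  names(per) <- measures
  membership <- table(unlist(per))
  membership <- stats::setNames(as.integer(membership), names(membership))
  all_nodes <- stats::setNames(integer(nrow(table)), table$node)
  all_nodes[names(membership)] <- membership
  list(per_measure = per, membership = all_nodes,
       union = sort(names(all_nodes)[all_nodes > 0]))
}
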