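# Brute-force oracles, independent of the package's graph routines.
# Graphs are represented as a named adjacency list built by raw edge-list
# scans; distances come from adjacency-matrix powers, path enumeration
# from depth-first search over simple paths.

random_simple_graph <- function(n, p, prefix = "N") {
  nodes <- sprintf("%s%02d", prefix, seq_len(n))
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(a = nodes[pairs[keep, 1L]],
                      b = nodes[pairs[keep, 2L]],
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

oracle_adjlist <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$a[i]; b <- edges$b[i]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# all-pairs distances via adjacency-matrix powers (independent of BFS)
oracle_distances <- function(nodes, edges) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges)))
    if (edges$a[i] != edges$b[i]) {
      A[edges$a[i], edges$b[i]] <- 1
      A[edges$b[i], edges$a[i]] <- 1
    }
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  P <- diag(n)
  for (k in seq_len(n - 1L)) {
    P <- P %*% A
    newly <- P > 0 & is.infinite(D)
    D[newly] <- k
    if (!any(is.infinite(D))) break
  }
  D
}

# every simple path from s to t of minimum length, by pruned DFS
oracle_all_shortest_paths <- function(adj, s, t) {
  best <- Inf
  found <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      len <- length(path) - 1L
      if (len < best) {
        best <<- len
        found <<- list(path)
      } else if (len == best) {
        found[[length(found) + 1L]] <<- path
      }
      return()
    }
    if (length(path) - 1L >= best) return()
    for (w in adj[[v]])
      if (!(w %in% path)) walk(c(path, w))
  }
  walk(s)
  list(length = if (is.finite(best)) best else Inf, paths = found)
}

oracle_betweenness <- function(nodes, edges) {
  adj <- oracle_adjlist(nodes, edges)
  cb <- stats::setNames(numeric(length(nodes)), nodes)
  pairs <- t(combn(nodes, 2))
  for (i in seq_len(nrow(pairs))) {
    s <- pairs[i, 1L]; t <- pairs[i, 2L]
    res <- oracle_all_shortest_paths(adj, s, t)
    if (length(res$paths) == 0L) next
    g_st <- length(res$paths)
    interior <- unlist(lapply(res$paths, function(p) p[-c(1L, length(p))]))
    if (length(interior) == 0L) next
    thru <- table(interior)
    cb[names(thru)] <- cb[names(thru)] + as.numeric(thru) / g_st
  }
  cb
}

oracle_closeness <- function(nodes, edges) {
  D <- oracle_distances(nodes, edges)
  vapply(nodes, function(v) {
    d <- D[v, setdiff(nodes, v)]
    d <- d[is.finite(d)]
    if (length(d) == 0L || sum(d) == 0) 0 else 1 / sum(d)
  }, 0)
}

oracle_degree_centrality <- function(nodes, edges) {
  deg <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    if (edges$a[i] == edges$b[i]) next
    deg[edges$a[i]] <- deg[edges$a[i]] + 1
    deg[edges$b[i]] <- deg[edges$b[i]] + 1
  }
  deg / (length(nodes) - 1)
}

oracle_eigenvector <- function(nodes, edges) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges)))
    if (edges$a[i] != edges$b[i]) {
      A[edges$a[i], edges$b[i]] <- 1
      A[edges$b[i], edges$a[i]] <- 1
    }
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- abs(v)
  stats::setNames(v / max(v), nodes)
}

# independent truth table for the dual-normalization reconciliation:
# per-variant category from fold change and significance, then the
# written-out 9-case direction table
oracle_dual_call <- function(fc_a, p_a, fc_b, p_b,
                             fc_thr = 1.5, p_thr = 0.05) {
  cat_of <- function(fc) {
    if (is.na(fc)) "below"
    else if (fc > fc_thr) "up"
    else if (fc < 1 / fc_thr) "down"
    else "below"
  }
  ca <- cat_of(fc_a); cb <- cat_of(fc_b)
  sig_a <- !is.na(p_a) && p_a < p_thr
  sig_b <- !is.na(p_b) && p_b < p_thr
  tab <- list(
    "up/up" = "up", "up/below" = "up", "below/up" = "up",
    "down/down" = "down", "down/below" = "down", "below/down" = "down",
    "up/down" = "not_de", "down/up" = "not_de", "below/below" = "not_de")
  dir <- tab[[paste(ca, cb, sep = "/")]]
  if (dir == "not_de") return("not_de")
  if (ca != "below" && !sig_a) return("not_de")
  if (cb != "below" && !sig_b) return("not_de")
  dir
}

# a small-but-complete generator configuration used across tests;
# ... overrides any base argument
tiny_config <- function(seed = 1L, ...) {
  args <- list(n_genes = 150L, n_sources = 4L, n_cytokines = 4L,
               n_tfs = 3L, n_hubs = 4L, hub_leaves = 6L,
               n_sensitive = 1L, n_datasets = 3L,
               n_disease = c(10L, 12L, 10L),
               n_control = c(10L, 9L, 10L),
               masked_per_dataset = c(0L, 6L, 0L), seed = seed)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

# noiseless variant: every emitted record is planted signal
noiseless_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, background_edge_prob = 0,
               unmapped_id_frac = 0, duplicate_edge_frac = 0,
               self_loop_frac = 0)
  do.call(tiny_config, utils::modifyList(args, list(...)))
}
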