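#' Write a gene graph to GraphML
#'
#' @param graph igraph graph.
#' @param path output path.
#' @param roles optional named list node -> character vector of roles;
#'   stored as a comma-joined `role` vertex attribute.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path, roles = NULL) {
  if (!is.null(roles)) {
    igraph::V(graph)$role <- vapply(igraph::V(graph)$name, function(v)
      paste(roles[[v]] %||% "", collapse = ","), "")
  }
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Write a gene graph to XGMML
#'
#' Minimal XGMML (eXtensible Graph Markup and Modelling Language) writer
#' producing files loadable in standard network viewers.
#'
#' @inheritParams write_graphml
#' @param label graph label attribute.
#' @return `path`, invisibly.
#' @export
write_xgmml <- function(graph, path, roles = NULL, label = "network") {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  vn <- igraph::V(graph)$name
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<graph label=\"%s\" directed=\"0\" xmlns=\"http://www.cs.rpi.edu/XGMML\">",
            esc(label))), con)
  for (i in seq_along(vn)) {
    role <- if (is.null(roles)) NULL else roles[[vn[i]]]
    open_tag <- sprintf("  <node id=\"%d\" label=\"%s\">", i, esc(vn[i]))
    if (is.null(role)) {
      writeLines(sub(">$", " />", open_tag), con)
    } else {
      writeLines(c(open_tag,
                   sprintf("    <att name=\"role\" type=\"string\" value=\"%s\" />",
                           esc(paste(role, collapse = ","))),
                   "  </node>"), con)
    }
  }
  el <- igraph::as_edgelist(graph, names = FALSE)
  for (i in seq_len(nrow(el)))
    writeLines(sprintf("  <edge source=\"%d\" target=\"%d\" />",
                       el[i, 1L], el[i, 2L]), con)
  writeLines("</graph>", con)
  invisible(path)
}

#' Count non-redundant interactions in an edge-list file
#'
#' Parses a plain edge-list file (two tab- or whitespace-separated
#' identifier columns per line, optional header, `#` comments), collapses
#' symmetric repeats and self-loops, and reports distinct undirected edge
#' and node counts. Suitable for auditing merged-interactome or network
#' edge-list exports.
#'
#' @param path file path.
#' @param header does the file carry a header line to skip? Default TRUE.
#' @return list with `n_edges`, `n_nodes`, `n_self_loops`, `n_records`.
#' @export
count_edge_list <- function(path, header = TRUE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (header && length(lines) > 0L) lines <- lines[-1L]
  if (length(lines) == 0L)
    return(list(n_edges = 0L, n_nodes = 0L, n_self_loops = 0L,
                n_records = 0L))
  fields <- strsplit(trimws(lines), "[\t ]+")
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  self <- a == b
  key <- paste(pmin(a[!self], b[!self]), pmax(a[!self], b[!self]))
  list(n_edges = length(unique(key)),
       n_nodes = length(unique(c(a, b))),
       n_self_loops = sum(self),
       n_records = length(a))
}

#' Count intermediates in an occurrence table file
#'
#' Parses a two-column (protein, occurrence count) TSV of shortest-path
#' intermediates and reports the number of distinct intermediates and the
#' total occurrence.
#'
#' @param path file path.
#' @param header skip a header line? Default TRUE.
#' @return list with `n_intermediates`, `total_occurrence`.
#' @export
count_intermediates_file <- function(path, header = TRUE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (header && length(lines) > 0L) lines <- lines[-1L]
  fields <- strsplit(trimws(lines), "[\t ]+")
  prot <- vapply(fields, `[[`, "", 1L)
  occ <- vapply(fields, function(f)
    if (length(f) >= 2L) suppressWarnings(as.numeric(f[[2L]]))
    else NA_real_, 0)
  list(n_intermediates = length(unique(prot)),
       total_occurrence = sum(occ, na.rm = TRUE))
}

#' Write per-node centrality results with top-set flags
#'
#' @param table centrality table from [centrality_table()].
#' @param top result of [top_fraction()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_centrality_report <- function(table, top, path) {
  out <- table
  for (m in names(top$per_measure))
    out[[paste0("top_", m)]] <- table$node %in% top$per_measure[[m]]
  out$n_measures <- unname(top$membership[table$node])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
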