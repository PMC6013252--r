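#' Read one interaction source table
#'
#' Reads an edge-list TSV for a single interaction database. The dialect is
#' a header row followed by one interaction per line with columns `id_a`,
#' `id_b` and an optional third `evidence` column; `#` lines are comments
#' and blank lines are skipped.
#'
#' @param path file path to the edge-list TSV.
#' @param source_name name of the source database, recorded per record.
#' @param namespace identifier namespace of the endpoints; one of
#'   `"symbol"`, `"accession"`, `"ensembl"`, `"custom"`.
#' @return data.frame of interaction records with columns `id_a`, `id_b`,
#'   `namespace`, `source`, `evidence` (NA when absent), in file order.
#' @export
read_interaction_source <- function(path, source_name,
                                    namespace = c("symbol", "accession",
                                                  "ensembl", "custom")) {
  namespace <- match.arg(namespace)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    warning("empty interaction file: ", path)
    return(data.frame(id_a = character(), id_b = character(),
                      namespace = character(), source = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  header <- keep[1L]
  body <- keep[-1L]
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- body[which(nf < 2L)[1L]]
    stop("malformed row (need >= 2 tab-separated fields) at line ", bad,
         " of ", path)
  }
  data.frame(
    id_a = trimws(vapply(fields, `[[`, "", 1L)),
    id_b = trimws(vapply(fields, `[[`, "", 2L)),
    namespace = namespace,
    source = source_name,
    evidence = vapply(fields, function(f)
      if (length(f) >= 3L) f[[3L]] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
}

#' Read an identifier-to-symbol mapping table
#'
#' Two-column TSV (identifier, gene symbol) with a header row. Symbols are
#' uppercased; rows with empty symbols are dropped. When one identifier
#' maps to several symbols, the first mapping in file order wins and a
#' warning reports the number of discarded alternatives.
#'
#' @param path file path.
#' @return named character vector: identifier -> gene symbol.
#' @export
read_id_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stop("id map needs two columns: ", path)
  ids <- trimws(tab[[1L]])
  sym <- norm_symbol(tab[[2L]])
  ok <- nzchar(ids) & nzchar(sym)
  ids <- ids[ok]; sym <- sym[ok]
  dup <- duplicated(ids)
  if (any(dup))
    warning(sum(dup), " identifier(s) with multiple mappings in ", path,
            "; first mapping kept")
  stats::setNames(sym[!dup], ids[!dup])
}

#' Map interaction records to gene-symbol space
#'
#' Records in the `symbol` namespace pass through with case normalization.
#' Otherwise both endpoints are looked up in `id_map`; a record either of
#' whose endpoints lacks a mapping is dropped and counted, never guessed.
#'
#' @param records data.frame from [read_interaction_source()].
#' @param id_map named character vector from [read_id_map()]; ignored for
#'   symbol-namespace records.
#' @return list with `records` (symbol-space data.frame: `symbol_a`,
#'   `symbol_b`, `source`, `evidence`) and `unmapped` (per-source named
#'   integer vector of dropped record counts).
#' @export
map_to_gene_symbols <- function(records, id_map = NULL) {
  if (nrow(records) == 0L) {
    return(list(records = data.frame(symbol_a = character(),
                                     symbol_b = character(),
                                     source = character(),
                                     evidence = character(),
                                     stringsAsFactors = FALSE),
                unmapped = integer()))
  }
  ns <- unique(records$namespace)
  if (length(ns) != 1L)
    stop("records must share one namespace; got: ", paste(ns, collapse = ", "))
  if (ns == "symbol") {
    sa <- norm_symbol(records$id_a)
    sb <- norm_symbol(records$id_b)
    keep <- nzchar(sa) & nzchar(sb)
  } else {
    if (is.null(id_map)) stop("id_map required for namespace ", ns)
    sa <- unname(id_map[records$id_a])
    sb <- unname(id_map[records$id_b])
    keep <- !is.na(sa) & !is.na(sb)
  }
  dropped <- tapply(!keep, records$source, sum)
  out <- data.frame(symbol_a = sa[keep], symbol_b = sb[keep],
                    source = records$source[keep],
                    evidence = records$evidence[keep],
                    stringsAsFactors = FALSE)
  list(records = out,
       unmapped = vapply(dropped, as.integer, integer(1L)))
}

#' Merge symbol-space interaction records into a non-redundant interactome
#'
#' Collapses A-B / B-A repeats onto one undirected edge stored in canonical
#' (lexicographically sorted) order, removes and counts self-loops, and
#' unions provenance over contributing sources. An optional evidence
#' predicate can drop records first (default accepts everything; sources
#' are assumed pre-filtered to experimentally determined physical
#' interactions).
#'
#' @param record_lists a symbol-space record data.frame, or a list of them
#'   (one per source), as produced by [map_to_gene_symbols()].
#' @param evidence_filter optional predicate over the evidence column;
#'   records for which it returns FALSE are dropped.
#' @return A `unified_ppi` list: `edges` (data.frame `symbol_a` <
#'   `symbol_b`, `sources` comma-joined), `n_self_loops`, `n_records_in`.
#' @export
merge_interactions <- function(record_lists, evidence_filter = NULL) {
  if (is.data.frame(record_lists)) record_lists <- list(record_lists)
  rec <- do.call(rbind, record_lists)
  if (is.null(rec) || nrow(rec) == 0L) {
    return(structure(list(
      edges = data.frame(symbol_a = character(), symbol_b = character(),
                         sources = character(), stringsAsFactors = FALSE),
      n_self_loops = 0L, n_records_in = 0L), class = "unified_ppi"))
  }
  n_in <- nrow(rec)
  if (!is.null(evidence_filter)) {
    keep <- vapply(rec$evidence, function(e) isTRUE(evidence_filter(e)), TRUE)
    rec <- rec[keep, , drop = FALSE]
  }
  a <- norm_symbol(rec$symbol_a)
  b <- norm_symbol(rec$symbol_b)
  self <- a == b
  n_self <- sum(self)
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  src <- rec$source[!self]
  key <- paste(a2, b2, sep = "\r")
  srcs <- vapply(split(src, key), function(s)
    paste(sort(unique(s)), collapse = ","), "")
  uk <- names(srcs)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  edges <- data.frame(
    symbol_a = vapply(parts, `[[`, "", 1L),
    symbol_b = vapply(parts, `[[`, "", 2L),
    sources = unname(srcs),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$symbol_a, edges$symbol_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, n_self_loops = n_self, n_records_in = n_in),
            class = "unified_ppi")
}

#' @export
print.unified_ppi <- function(x, ...) {
  cat("Unified PPI:", nrow(x$edges), "non-redundant edges from",
      x$n_records_in, "records (", x$n_self_loops, "self-loops removed)\n")
  invisible(x)
}

#' Write a merged interactome to TSV
#' @param ppi `unified_ppi` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_unified_ppi <- function(ppi, path) {
  write.table(ppi$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a merged interactome from TSV
#' @param path path written by [write_unified_ppi()], or any TSV with
#'   columns `symbol_a`, `symbol_b` (and optionally `sources`).
#' @return `unified_ppi` object
#' @export
read_unified_ppi <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("symbol_a", "symbol_b") %in% names(tab)))
    stop("expected columns symbol_a, symbol_b in ", path)
  if (is.null(tab$sources)) tab$sources <- "unknown"
  rec <- data.frame(symbol_a = tab$symbol_a, symbol_b = tab$symbol_b,
                    source = tab$sources, evidence = NA_character_,
                    stringsAsFactors = FALSE)
  merge_interactions(rec)
}

#' Integrate multiple interaction sources end to end
#'
#' Convenience wrapper: read each source, map to symbols, merge.
#'
#' @param sources data.frame with columns `name`, `namespace`, `path`.
#' @param id_map named identifier -> symbol vector (for non-symbol sources).
#' @return list with `ppi` (`unified_ppi`) and `unmapped` (per-source
#'   dropped-record counts).
#' @export
integrate_sources <- function(sources, id_map = NULL) {
  mapped <- list()
  unmapped <- integer()
  for (i in seq_len(nrow(sources))) {
    rec <- read_interaction_source(sources$path[i], sources$name[i],
                                   sources$namespace[i])
    m <- map_to_gene_symbols(rec, id_map)
    mapped[[i]] <- m$records
    unmapped <- c(unmapped, m$unmapped)
  }
  list(ppi = merge_interactions(mapped), unmapped = unmapped)
}
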