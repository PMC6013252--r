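#' Construct an expression dataset
#'
#' Container for one microarray dataset in one normalization variant:
#' a genes x samples matrix, a disease/control group label per sample, a
#' scale tag saying whether values are linear or log2, and a normalization
#' tag ("A"/"B") identifying which of the two normalization pipelines
#' produced the matrix (standing for the RMA/MAS5 pair of a real study).
#'
#' @param name dataset name.
#' @param matrix numeric matrix, rownames = gene symbols, colnames =
#'   sample ids.
#' @param groups named character vector sample -> "disease"/"control", or a
#'   character vector aligned with the matrix columns.
#' @param scale_tag "linear" or "log2".
#' @param normalization_tag "A" or "B".
#' @return An `expression_dataset` list.
#' @export
expression_dataset <- function(name, matrix, groups,
                               scale_tag = c("log2", "linear"),
                               normalization_tag = c("A", "B")) {
  scale_tag <- match.arg(scale_tag)
  normalization_tag <- match.arg(normalization_tag)
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("expression matrix needs gene rownames and sample colnames")
  rownames(matrix) <- norm_symbol(rownames(matrix))
  if (is.null(names(groups))) {
    if (length(groups) != ncol(matrix))
      stop("groups must be named by sample or aligned with columns")
    names(groups) <- colnames(matrix)
  }
  missing <- setdiff(colnames(matrix), names(groups))
  if (length(missing))
    stop("samples without group labels: ", paste(missing, collapse = ", "))
  groups <- groups[colnames(matrix)]
  if (!all(groups %in% c("disease", "control")))
    stop("groups must be 'disease' or 'control'")
  structure(list(name = name, matrix = matrix, groups = groups,
                 scale_tag = scale_tag,
                 normalization_tag = normalization_tag),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset '%s' [%s/%s]: %d genes x %d samples (%d disease, %d control)\n",
              x$name, x$normalization_tag, x$scale_tag, nrow(x$matrix),
              ncol(x$matrix), sum(x$groups == "disease"),
              sum(x$groups == "control")))
  invisible(x)
}

#' Read an expression matrix TSV plus its sample annotation
#'
#' The matrix dialect is a header row (`gene` then sample ids) and one gene
#' per line; the annotation is a two-column TSV `sample_id`, `group`.
#'
#' @param name dataset name.
#' @param matrix_path expression TSV path.
#' @param annot_path sample-annotation TSV path.
#' @inheritParams expression_dataset
#' @return `expression_dataset`
#' @export
read_expression_dataset <- function(name, matrix_path, annot_path,
                                    scale_tag = "log2",
                                    normalization_tag = "A") {
  tab <- read.delim(matrix_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- tab[[1L]]
  ann <- read.delim(annot_path, stringsAsFactors = FALSE)
  groups <- stats::setNames(ann$group, ann$sample_id)
  expression_dataset(name, mat, groups, scale_tag, normalization_tag)
}

#' Build a localization table
#'
#' @param annotations named list: gene symbol -> character vector of
#'   compartment labels (e.g. "plasma membrane", "cytoplasm", "nucleus").
#' @param whitelist symbols exempt from annotation (receptors and
#'   transcription factors known to act at the membrane/cytoplasm but
#'   absent from the localization resource).
#' @return A `localization_table` list.
#' @export
localization_table <- function(annotations, whitelist = character()) {
  names(annotations) <- norm_symbol(names(annotations))
  structure(list(annotations = annotations,
                 whitelist = norm_symbol(whitelist)),
            class = "localization_table")
}

#' Read a localization table (and optional whitelist) from TSV
#'
#' Dialect: columns `symbol`, `compartments` (comma-joined labels).
#' The whitelist file is one symbol per line.
#'
#' @param path localization TSV path.
#' @param whitelist_path optional whitelist path.
#' @return `localization_table`
#' @export
read_localization_table <- function(path, whitelist_path = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  ann <- lapply(strsplit(tab$compartments, ","), trimws)
  names(ann) <- tab$symbol
  wl <- if (!is.null(whitelist_path)) readLines(whitelist_path) else character()
  wl <- wl[nzchar(trimws(wl))]
  localization_table(ann, wl)
}

#' Restrict an interactome to plasma-membrane / cytoplasmic proteins
#'
#' An endpoint passes if it is annotated to at least one allowed
#' compartment or is whitelisted; an edge is kept iff both endpoints pass.
#' The retained gene universe (the "G-list") is returned alongside.
#'
#' @param ppi `unified_ppi`.
#' @param loc `localization_table`.
#' @param allowed_compartments compartments that qualify; default plasma
#'   membrane and cytoplasm.
#' @return list with `ppi` (filtered `unified_ppi`), `g_list` (character
#'   vector of retained genes), `n_dropped_edges`.
#' @export
localization_filter <- function(ppi, loc,
                                allowed_compartments = c("plasma membrane",
                                                         "cytoplasm")) {
  if (length(allowed_compartments) == 0L)
    stop("allowed_compartments must be non-empty")
  passes <- function(sym) {
    sym %in% loc$whitelist ||
      any(loc$annotations[[sym]] %in% allowed_compartments)
  }
  syms <- unique(c(ppi$edges$symbol_a, ppi$edges$symbol_b))
  ok <- stats::setNames(vapply(syms, passes, TRUE), syms)
  keep <- ok[ppi$edges$symbol_a] & ok[ppi$edges$symbol_b]
  out <- ppi
  out$edges <- ppi$edges[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  g_list <- sort(unique(c(out$edges$symbol_a, out$edges$symbol_b)))
  list(ppi = out, g_list = g_list, n_dropped_edges = sum(!keep))
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r of two equal-length vectors; returns `NA` (the
#' undefined marker) when either vector has zero variance.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1], or NA.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Co-expression configuration
#'
#' @param r_threshold signed Pearson threshold (strict `>`); default 0.7.
#' @param min_datasets minimum number of datasets in which the threshold
#'   must be exceeded; default 1.
#' @param sample_scope correlate over `"disease_only"` (default) or
#'   `"all"` samples.
#' @param normalization_used which normalization variant to correlate on;
#'   default `"A"` (the RMA-standing variant).
#' @return a `coexpression_config` list.
#' @export
coexpression_config <- function(r_threshold = 0.7, min_datasets = 1L,
                                sample_scope = c("disease_only", "all"),
                                normalization_used = "A") {
  if (r_threshold <= -1 || r_threshold >= 1)
    stop("r_threshold must be in (-1, 1)")
  structure(list(r_threshold = r_threshold,
                 min_datasets = as.integer(min_datasets),
                 sample_scope = match.arg(sample_scope),
                 normalization_used = normalization_used),
            class = "coexpression_config")
}

# Per-edge Pearson r within one dataset, vectorized over edges.
# Edges with an endpoint absent from the matrix, or with < 2 samples in
# scope, contribute NA (no evidence).
edge_correlations <- function(edges, dataset, cfg) {
  samp <- if (cfg$sample_scope == "disease_only")
    names(dataset$groups)[dataset$groups == "disease"]
  else names(dataset$groups)
  if (length(samp) < 2L)
    return(rep(NA_real_, nrow(edges)))
  mat <- dataset$matrix[, samp, drop = FALSE]
  r <- rep(NA_real_, nrow(edges))
  present <- edges$symbol_a %in% rownames(mat) &
    edges$symbol_b %in% rownames(mat)
  if (!any(present)) return(r)
  xa <- mat[edges$symbol_a[present], , drop = FALSE]
  xb <- mat[edges$symbol_b[present], , drop = FALSE]
  n <- ncol(mat)
  za <- xa - rowMeans(xa)
  zb <- xb - rowMeans(xb)
  sa <- sqrt(rowSums(za^2))
  sb <- sqrt(rowSums(zb^2))
  num <- rowSums(za * zb)
  val <- ifelse(sa == 0 | sb == 0, NA_real_, num / (sa * sb))
  r[present] <- val
  r
}

#' Filter interactome edges by disease-sample co-expression
#'
#' An edge is retained iff its endpoints' expression profiles correlate
#' with Pearson r strictly above the threshold (signed, not absolute) in
#' at least `min_datasets` of the supplied datasets. Correlation uses the
#' configured normalization variant and sample scope (disease samples by
#' default). Datasets in which an endpoint is not measured contribute no
#' evidence for that edge.
#'
#' @param ppi `unified_ppi` (typically localization-filtered).
#' @param datasets list of `expression_dataset` objects; only those whose
#'   `normalization_tag` matches the config are used.
#' @param cfg `coexpression_config`.
#' @return list with `ppi` (retained edges as `unified_ppi`), `r_table`
#'   (data.frame: edge endpoints, per-dataset r, `max_r`, `n_pass`).
#' @export
coexpression_filter <- function(ppi, datasets, cfg = coexpression_config()) {
  use <- Filter(function(d) d$normalization_tag == cfg$normalization_used,
                datasets)
  if (length(use) == 0L)
    stop("no dataset with normalization_tag '", cfg$normalization_used, "'")
  edges <- ppi$edges
  rmat <- vapply(use, function(d) edge_correlations(edges, d, cfg),
                 numeric(nrow(edges)))
  rmat <- matrix(rmat, nrow = nrow(edges))
  colnames(rmat) <- vapply(use, `[[`, "", "name")
  n_pass <- rowSums(rmat > cfg$r_threshold, na.rm = TRUE)
  keep <- n_pass >= cfg$min_datasets
  max_r <- suppressWarnings(apply(rmat, 1L, max, na.rm = TRUE))
  max_r[!is.finite(max_r)] <- NA_real_
  r_table <- data.frame(symbol_a = edges$symbol_a,
                        symbol_b = edges$symbol_b,
                        rmat, max_r = max_r, n_pass = n_pass,
                        check.names = FALSE, stringsAsFactors = FALSE)
  out <- ppi
  out$edges <- edges[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  list(ppi = out, r_table = r_table)
}
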