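#' Cytokine signaling specification for rheumatoid arthritis synovial
#' fibroblasts
#'
#' The packaged literature-curated signaling specification: 12 cytokines
#' known to be active in RA synovial fibroblasts, the genes encoding their
#' receptors, and the transcription factors (with their subunit genes) each
#' cytokine activates. One row per cytokine/transcription-factor pairing;
#' receptor and subunit gene lists are comma-joined.
#'
#' @return A data.frame with columns `cytokine`, `receptors` (comma-joined
#'   gene symbols), `tf_name`, `tf_genes` (comma-joined gene symbols).
#' @seealso [enumerate_receptor_tf_pairs()] for expanding rows into
#'   receptor-gene x subunit-gene combinations.
#' @export
#' @examples
#' spec <- signaling_spec_rasf()
#' nrow(spec)  # 29 cytokine/TF pairings
signaling_spec_rasf <- function() {
  nfkb <- "NFKB1,NFKB2,RELA,RELB,REL"
  ap1  <- "JUN,JUNB,FOS,FOSB,FOSL1,FOSL2"
  tnfr <- "TNFRSF1A,TNFRSF1B"
  il17r <- "IL17RA,IL17RC"
  ifnar <- "IFNAR1,IFNAR2"
  tgfbr <- "TGFBR1,TGFBR2"
  rows <- list(
    list("TNF",       tnfr,            "NF-kB", nfkb),
    list("IL-18",     "IL18R1,IL18RAP","NF-kB", nfkb),
    list("IL-17",     il17r,           "NF-kB", nfkb),
    list("IL-27",     "IL27RA,IL6ST",  "STAT1", "STAT1"),
    list("IL-1a/b",   "IL1R1",         "NF-kB", nfkb),
    list("TNF",       tnfr,            "AP-1",  ap1),
    list("IL-1b",     "IL1R1",         "AP-1",  ap1),
    list("IL-17",     il17r,           "AP-1",  ap1),
    list("TNF",       tnfr,            "IRF3",  "IRF3"),
    list("TNFSF14",   "TNFRSF14",      "NF-kB", nfkb),
    list("IL-33",     "IL1RL1",        "NF-kB", nfkb),
    list("IL-17",     il17r,           "STAT3", "STAT3"),
    list("IL-1b",     "IL1R1",         "STAT1", "STAT1"),
    list("IFNa/b",    ifnar,           "STAT1", "STAT1"),
    list("IFNg",      "IFNGR1,IFNGR2", "STAT1", "STAT1"),
    list("TNF",       tnfr,            "STAT1", "STAT1"),
    list("IL-1a/b",   "IL1R1",         "IRF3",  "IRF3"),
    list("IL-1a/b",   "IL1R1",         "IRF7",  "IRF7"),
    list("IFNa/b",    ifnar,           "IRF3",  "IRF3"),
    list("IFNa/b",    ifnar,           "IRF7",  "IRF7"),
    list("TNF",       tnfr,            "IRF1",  "IRF1"),
    list("IL-1b",     "IL1R1",         "IRF1",  "IRF1"),
    list("TGF-b1",    tgfbr,           "NF-kB", nfkb),
    list("TGF-b1",    tgfbr,           "AP-1",  ap1),
    list("TGF-b1",    tgfbr,           "SMAD",  "SMAD2,SMAD3"),
    list("IL-21",     "IL2RG",         "STAT3", "STAT3"),
    list("IL6",       "IL6R",          "STAT3", "STAT3"),
    list("TNF",       tnfr,            "STAT3", "STAT3"),
    list("IL-27",     "IL27RA,IL6ST",  "AP-1",  ap1)
  )
  out <- data.frame(
    cytokine  = vapply(rows, `[[`, "", 1L),
    receptors = vapply(rows, `[[`, "", 2L),
    tf_name   = vapply(rows, `[[`, "", 3L),
    tf_genes  = vapply(rows, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
  validate_signaling_spec(out)
}

#' Validate a signaling specification table
#'
#' Checks the column contract and the non-emptiness of receptor and subunit
#' gene lists, and uppercases all gene symbols.
#'
#' @param spec data.frame with columns `cytokine`, `receptors`, `tf_name`,
#'   `tf_genes`.
#' @return The validated (symbol-normalized) spec.
#' @export
validate_signaling_spec <- function(spec) {
  needed <- c("cytokine", "receptors", "tf_name", "tf_genes")
  if (!all(needed %in% names(spec)))
    stop("signaling spec must have columns: ", paste(needed, collapse = ", "))
  spec$receptors <- vapply(strsplit(spec$receptors, ","),
                           function(g) paste(norm_symbol(g), collapse = ","), "")
  spec$tf_genes <- vapply(strsplit(spec$tf_genes, ","),
                          function(g) paste(norm_symbol(g), collapse = ","), "")
  if (any(!nzchar(spec$receptors)) || any(!nzchar(spec$tf_genes)))
    stop("receptor and tf gene lists must be non-empty")
  spec
}

#' Split comma-joined gene lists of a signaling-spec column
#' @param x character vector of comma-joined symbols
#' @return list of character vectors
#' @keywords internal
split_genes <- function(x) lapply(strsplit(x, ","), norm_symbol)

#' Current rheumatoid arthritis drug-target gene list
#'
#' The packaged ensemble of 48 genes encoding established or investigated
#' RA drug targets (successful drugs, clinical trials and research
#' projects), as curated from the Therapeutic Target Database together with
#' targets of approved RA drugs reported in the genetics literature.
#'
#' @return Character vector of 48 gene symbols.
#' @export
ra_drug_targets <- function() {
  c("IKBKB", "CHUK", "CFLAR", "JUN", "ITGB1", "IL6R", "FGF2", "CCL2",
    "ITGA4", "OSM", "MIF", "IL1R1", "LIF", "MMP8", "IL13", "PTGS2",
    "IL6ST", "IL15", "CTSK", "SYK", "JAK3", "MAPK12", "F2RL1", "IL2",
    "DHODH", "IKBKE", "MYD88", "TLR9", "TNF", "CD80", "CD86", "MS4A1",
    "PRDX5", "HPRT1", "CAMLG", "PPP3R2", "ELANE", "DHFR", "ALOX5",
    "PTGS1", "PPARG", "FKBP1A", "MTOR", "JAK1", "JAK2", "NR3C1",
    "NR3C2", "TLR7")
}

#' Read a signaling specification from TSV
#'
#' Expects columns cytokine, receptors, tf_name, tf_genes with
#' comma-joined gene lists (the dialect written by [write_signaling_spec()]).
#'
#' @param path file path
#' @return validated signaling-spec data.frame
#' @export
read_signaling_spec <- function(path) {
  validate_signaling_spec(
    read.delim(path, stringsAsFactors = FALSE, comment.char = "#"))
}

#' Write a signaling specification to TSV
#' @param spec signaling-spec data.frame
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_signaling_spec <- function(spec, path) {
  write.table(spec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
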