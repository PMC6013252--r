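#' Differential-expression configuration
#'
#' @param p_threshold two-sided p-value cut (strict `<`); default 0.05.
#' @param fc_threshold linear fold-change cut (strict `>`); default 1.5.
#' @param variance_assumption "pooled" (classical two-sample t-test,
#'   default) or "welch".
#' @param p_rule "crossing_variants" (default: the p cut must hold in
#'   every normalization variant whose fold change crossed the threshold)
#'   or "any_variant" (p cut in at least one variant suffices).
#' @return a `de_config` list.
#' @export
de_config <- function(p_threshold = 0.05, fc_threshold = 1.5,
                      variance_assumption = c("pooled", "welch"),
                      p_rule = c("crossing_variants", "any_variant")) {
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold in (0,1)")
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1")
  structure(list(p_threshold = p_threshold, fc_threshold = fc_threshold,
                 variance_assumption = match.arg(variance_assumption),
                 p_rule = match.arg(p_rule)),
            class = "de_config")
}

#' Two-sample independent t-test
#'
#' Two-sided test of equal group means; pooled-variance (classical) or
#' Welch per the variance assumption. When neither group varies the
#' statistic is undefined and NA is returned (the gene is untestable).
#'
#' @param disease,control numeric vectors, each of length >= 2.
#' @param variance_assumption "pooled" or "welch".
#' @return list with `t` and `p` (both NA when undefined).
#' @export
two_sample_ttest <- function(disease, control,
                             variance_assumption = c("pooled", "welch")) {
  variance_assumption <- match.arg(variance_assumption)
  if (length(disease) < 2L || length(control) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(disease) == 0 && stats::sd(control) == 0)
    return(list(t = NA_real_, p = NA_real_))
  tt <- tryCatch(
    stats::t.test(disease, control,
                  var.equal = variance_assumption == "pooled"),
    error = function(e) NULL)
  if (is.null(tt)) return(list(t = NA_real_, p = NA_real_))
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Fold change between disease and control group means
#'
#' Ratio of arithmetic group means on linear scale; log2-tagged data are
#' unlogged first. Undefined (NA) when the control mean is not positive.
#'
#' @param disease,control numeric vectors.
#' @param scale_tag "linear" or "log2".
#' @return linear-scale ratio mean(disease)/mean(control), or NA.
#' @export
fold_change <- function(disease, control, scale_tag = c("log2", "linear")) {
  scale_tag <- match.arg(scale_tag)
  if (scale_tag == "log2") {
    disease <- 2^disease
    control <- 2^control
  }
  mc <- mean(control)
  if (!is.finite(mc) || mc <= 0) return(NA_real_)
  mean(disease) / mc
}

# Per-variant direction category from a fold change: which side of the
# threshold pair (fc_threshold, 1/fc_threshold) the ratio falls on.
# NA fold changes count as "below" (no evidence from that variant).
fc_category <- function(fc, fc_threshold) {
  if (is.na(fc)) return("below")
  if (fc > fc_threshold) "up"
  else if (fc < 1 / fc_threshold) "down"
  else "below"
}

#' Reconcile differential expression across two normalization variants
#'
#' A gene is called up-regulated in a dataset iff it is up in both
#' normalization variants, or up in one and below the fold-change
#' threshold in the other; down-regulation is symmetric. Opposite
#' directions in the two variants, or neither variant crossing the
#' threshold, give `not_de`. Under the default p rule the p cut must hold
#' in every variant whose fold change crossed the threshold.
#'
#' @param stats_a,stats_b lists with elements `p` and `fc` for the two
#'   normalization variants of the same dataset.
#' @param cfg `de_config`.
#' @return list with `direction` ("up"/"down"/"not_de"), `p_a`, `p_b`,
#'   `fc_a`, `fc_b`.
#' @export
call_de_dual <- function(stats_a, stats_b, cfg = de_config()) {
  cat_a <- fc_category(stats_a$fc, cfg$fc_threshold)
  cat_b <- fc_category(stats_b$fc, cfg$fc_threshold)
  sig <- function(p) !is.na(p) && p < cfg$p_threshold
  direction <- "not_de"
  for (dir in c("up", "down")) {
    agree <- (cat_a == dir && cat_b == dir) ||
      (cat_a == dir && cat_b == "below") ||
      (cat_a == "below" && cat_b == dir)
    if (!agree) next
    p_ok <- switch(cfg$p_rule,
      crossing_variants = (cat_a != dir || sig(stats_a$p)) &&
        (cat_b != dir || sig(stats_b$p)),
      any_variant = sig(stats_a$p) || sig(stats_b$p))
    if (p_ok) direction <- dir
  }
  list(direction = direction, p_a = stats_a$p, p_b = stats_b$p,
       fc_a = stats_a$fc, fc_b = stats_b$fc)
}

# t-test + fold change for one gene in one expression_dataset variant.
variant_stats <- function(dataset, gene, cfg) {
  if (!(gene %in% rownames(dataset$matrix)))
    return(list(p = NA_real_, fc = NA_real_))
  x <- dataset$matrix[gene, ]
  disease <- x[dataset$groups == "disease"]
  control <- x[dataset$groups == "control"]
  if (length(disease) < 2L || length(control) < 2L)
    return(list(p = NA_real_, fc = NA_real_))
  tt <- two_sample_ttest(disease, control, cfg$variance_assumption)
  list(p = tt$p, fc = fold_change(disease, control, dataset$scale_tag))
}

#' Call differential expression for genes across paired-variant datasets
#'
#' @param dataset_pairs list of lists, each with `name`, `A` and `B`
#'   (`expression_dataset` objects for the two normalization variants of
#'   one dataset).
#' @param genes gene symbols to test.
#' @param cfg `de_config`.
#' @return long-format data.frame: `gene`, `dataset`, `direction`, `p_a`,
#'   `p_b`, `fc_a`, `fc_b`.
#' @export
run_diffexpr <- function(dataset_pairs, genes, cfg = de_config()) {
  genes <- norm_symbol(genes)
  rows <- vector("list", length(dataset_pairs) * length(genes))
  k <- 0L
  for (dp in dataset_pairs) {
    for (g in genes) {
      call <- call_de_dual(variant_stats(dp$A, g, cfg),
                           variant_stats(dp$B, g, cfg), cfg)
      k <- k + 1L
      rows[[k]] <- data.frame(gene = g, dataset = dp$name,
                              direction = call$direction,
                              p_a = call$p_a, p_b = call$p_b,
                              fc_a = call$fc_a, fc_b = call$fc_b,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene differential-expression profile
#'
#' Summarizes a long-format DE table into per-gene, per-dataset directions
#' and the count of datasets in which each gene is differentially
#' expressed (direction != not_de; untestable datasets count as not_de).
#'
#' @param de_table data.frame from [run_diffexpr()].
#' @return list with `directions` (genes x datasets character matrix) and
#'   `counts` (named integer vector gene -> number of DE datasets).
#' @export
de_profile <- function(de_table) {
  genes <- unique(de_table$gene)
  datasets <- unique(de_table$dataset)
  mat <- matrix("not_de", length(genes), length(datasets),
                dimnames = list(genes, datasets))
  idx <- cbind(match(de_table$gene, genes),
               match(de_table$dataset, datasets))
  mat[idx] <- de_table$direction
  counts <- rowSums(mat != "not_de")
  list(directions = mat,
       counts = stats::setNames(as.integer(counts), genes))
}

#' Per-gene consensus direction across datasets
#'
#' Majority direction over the datasets where the gene is called DE; an
#' exact up/down tie (or no DE dataset) gives `"none"`.
#'
#' @param directions genes x datasets character matrix (see [de_profile()]).
#' @return named character vector gene -> "up"/"down"/"none".
#' @export
consensus_direction <- function(directions) {
  apply(directions, 1L, function(d) {
    n_up <- sum(d == "up"); n_dn <- sum(d == "down")
    if (n_up > n_dn) "up" else if (n_dn > n_up) "down" else "none"
  })
}
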