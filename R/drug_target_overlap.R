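#' Observed overlap and direct-link statistics
#'
#' Statistic 1: how many key genes are in the drug-target list (list
#' membership; targets need not be network nodes). Statistic 2: after
#' removing those overlaps, how many of the remaining key genes have at
#' least one network neighbor in the target list (only targets present in
#' the network can be neighbors).
#'
#' @param cppin igraph graph (the cytokine network).
#' @param keys key gene symbols (must be nodes of `cppin`).
#' @param targets drug-target gene symbols.
#' @return list with `n_overlap`, `overlap_genes`, `n_direct`,
#'   `direct_links` (named list non-target key -> adjacent targets).
#' @export
observed_stats <- function(cppin, keys, targets) {
  keys <- norm_symbol(keys)
  targets <- norm_symbol(targets)
  vn <- igraph::V(cppin)$name
  missing <- setdiff(keys, vn)
  if (length(missing))
    stop("keys not in network: ", paste(missing, collapse = ", "))
  overlap_genes <- sort(intersect(keys, targets))
  rest <- setdiff(keys, targets)
  links <- lapply(rest, function(k) {
    nb <- vn[as.integer(igraph::adjacent_vertices(cppin, k)[[1L]])]
    sort(intersect(nb, targets))
  })
  names(links) <- rest
  links <- links[lengths(links) > 0L]
  list(n_overlap = length(overlap_genes), overlap_genes = overlap_genes,
       n_direct = length(links), direct_links = links)
}

#' Monte-Carlo null for drug-target overlap and direct links
#'
#' Draws `n_samples` uniform samples of `k` distinct nodes from the whole
#' network, computes both statistics exactly as [observed_stats()] does
#' (overlaps removed before direct-link counting), and reports upper-tail
#' empirical p-values for the observed values: raw r/n (the comparison
#' surface) and the add-one corrected (r+1)/(n+1).
#'
#' @param cppin igraph graph.
#' @param k sample size per draw (the key-set size).
#' @param targets drug-target gene symbols.
#' @param observed_overlap,observed_direct observed statistic values.
#' @param n_samples number of Monte-Carlo draws; default 1e6.
#' @param seed RNG seed (the draw stream is local to this call).
#' @return A `resampling_result` list: `p_overlap`, `p_direct` (raw),
#'   `p_overlap_add1`, `p_direct_add1`, `se_overlap`, `se_direct`
#'   (binomial standard errors), `n_samples`, `seed`, the null counts
#'   `n_ge_overlap`, `n_ge_direct`, and the full null distributions
#'   `overlap_tally`, `direct_tally` (counts of statistic values 0..k).
#' @export
resample_null <- function(cppin, k, targets, observed_overlap,
                          observed_direct = NULL, n_samples = 1e6,
                          seed = 1L) {
  vn <- igraph::V(cppin)$name
  n <- length(vn)
  if (k > n) stop("k exceeds number of network nodes")
  targets <- norm_symbol(targets)
  is_target <- vn %in% targets
  if (!any(is_target)) {
    flagged <- list(p_overlap = 1, p_direct = 1, p_overlap_add1 = 1,
                    p_direct_add1 = 1, se_overlap = 0, se_direct = 0,
                    n_samples = as.integer(n_samples), seed = seed,
                    n_ge_overlap = as.integer(n_samples),
                    n_ge_direct = as.integer(n_samples),
                    empty_targets = TRUE)
    return(structure(flagged, class = "resampling_result"))
  }
  # per-node attributes fully determine both statistics for a draw
  adj_target <- vapply(seq_len(n), function(i) {
    nb <- as.integer(igraph::adjacent_vertices(cppin, i)[[1L]])
    any(is_target[nb])
  }, TRUE)
  direct_eligible <- !is_target & adj_target
  ov_tally <- integer(k + 1L)   # counts of overlap = 0..k
  di_tally <- integer(k + 1L)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  n_samples <- as.integer(n_samples)
  for (i in seq_len(n_samples)) {
    idx <- sample.int(n, k)
    ov <- sum(is_target[idx])
    ov_tally[ov + 1L] <- ov_tally[ov + 1L] + 1L
    # conditioning as in observed_stats: overlaps removed before counting
    dl <- sum(direct_eligible[idx])
    di_tally[dl + 1L] <- di_tally[dl + 1L] + 1L
  }
  ge_overlap <- sum(ov_tally[(observed_overlap + 1L):(k + 1L)])
  ge_direct <- if (is.null(observed_direct)) NA_integer_
               else sum(di_tally[(observed_direct + 1L):(k + 1L)])
  p_ov <- ge_overlap / n_samples
  p_di <- if (is.null(observed_direct)) NA_real_ else ge_direct / n_samples
  structure(list(
    p_overlap = p_ov,
    p_direct = p_di,
    p_overlap_add1 = (ge_overlap + 1) / (n_samples + 1),
    p_direct_add1 = if (is.null(observed_direct)) NA_real_
                    else (ge_direct + 1) / (n_samples + 1),
    se_overlap = sqrt(p_ov * (1 - p_ov) / n_samples),
    se_direct = if (is.null(observed_direct)) NA_real_
                else sqrt(p_di * (1 - p_di) / n_samples),
    n_samples = n_samples, seed = seed,
    n_ge_overlap = ge_overlap, n_ge_direct = ge_direct,
    overlap_tally = ov_tally, direct_tally = di_tally,
    empty_targets = FALSE), class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo null (%d draws, seed %s):\n  p_overlap = %.4g (SE %.2g)\n",
              x$n_samples, format(x$seed), x$p_overlap, x$se_overlap))
  if (!is.na(x$p_direct))
    cat(sprintf("  p_direct  = %.4g (SE %.2g)\n", x$p_direct, x$se_direct))
  invisible(x)
}

#' Upper-tail hypergeometric probability by direct summation
#'
#' P(X >= x) when drawing `k` of `N` items of which `K` are marked,
#' computed by summing the point masses exp(log-choose terms) directly —
#' an independent closed form for the membership-only overlap statistic.
#'
#' @param N population size.
#' @param K number of marked items.
#' @param k draw size.
#' @param x threshold.
#' @return probability in [0, 1].
#' @export
hypergeometric_tail <- function(N, K, k, x) {
  if (K < 0 || K > N || k < 0 || k > N || x < 0 || x > k)
    stop("require 0 <= K <= N, 0 <= k <= N, 0 <= x <= k")
  lo <- max(x, 0)
  hi <- min(k, K)
  if (lo > hi) return(0)
  i <- lo:hi
  sum(exp(lchoose(K, i) + lchoose(N - K, k - i) - lchoose(N, k)))
}
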