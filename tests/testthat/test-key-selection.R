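test_that("the two-clause key rule selects as stated", {
  membership <- c(A = 4L, B = 2L, C = 2L, D = 3L, E = 0L)
  de <- c(A = 5L, B = 3L, C = 4L, D = 3L, E = 5L)
  sel <- select_key_molecules(membership, de)
  expect_setequal(sel$keys, c("A", "C", "D"))   # B fails both clauses
  rep <- sel$report
  expect_equal(rep$clause[rep$gene == "A"], 1L)
  expect_equal(rep$clause[rep$gene == "C"], 2L)
  expect_true(is.na(rep$clause[rep$gene == "E"]))
})

test_that("selection is monotone in membership and DE counts", {
  set.seed(51)
  for (rep in 1:100) {
    m <- sample(0:4, 1L); d <- sample(0:5, 1L)
    sel1 <- select_key_molecules(c(G = m), c(G = d))
    sel2 <- select_key_molecules(c(G = min(m + 1L, 4L)),
                                 c(G = min(d + 1L, 5L)))
    if (length(sel1$keys)) expect_length(sel2$keys, 1L)
  }
})

test_that("pathway directionality labels follow the count rules", {
  mk_ps <- function(mols) structure(
    list(source = mols[1L], target = mols[length(mols)],
         length = length(mols) - 1L, paths = list(mols)),
    class = "path_set")
  pt <- data.frame(cytokine = "CY", tf_name = "TF",
                   receptor = "R", tf_gene = "T")
  sets <- stats::setNames(list(mk_ps(c("R", "X", "Y", "Z", "T"))), "R\rT")
  all_up <- c(R = "up", X = "up", Y = "up", Z = "up", T = "up")
  d1 <- classify_path_directionality(sets, pt, all_up)
  expect_equal(d1$label, "exclusively_up")
  expect_equal(d1$n_up, 5L)
  mostly <- c(R = "up", X = "up", Y = "up", Z = "up", T = "down")
  expect_equal(classify_path_directionality(sets, pt, mostly)$label,
               "mostly_up")
  none <- c(R = "none", X = "none", Y = "none", Z = "none", T = "none")
  expect_equal(classify_path_directionality(sets, pt, none)$label, "no_de")
  # swapping every call flips the label polarity
  flipped <- ifelse(mostly == "up", "down", ifelse(mostly == "down",
                                                   "up", "none"))
  names(flipped) <- names(mostly)
  expect_equal(classify_path_directionality(sets, pt, flipped)$label,
               "mostly_down")
  mixed <- c(R = "up", X = "up", Y = "down", Z = "down", T = "none")
  expect_equal(classify_path_directionality(sets, pt, mixed)$label, "mixed")
})

test_that("well-separated groups cluster perfectly; degenerate input is stable", {
  set.seed(53)
  n <- 6L
  sig <- c(rep(2, 5), rep(-2, 5))
  mat <- cbind(
    sapply(seq_len(n), function(i) 5 + sig + rnorm(10, 0, 0.2)),
    sapply(seq_len(n), function(i) 5 - sig + rnorm(10, 0, 0.2)))
  rownames(mat) <- sprintf("K%02d", 1:10)
  colnames(mat) <- sprintf("S%02d", 1:12)
  ds <- expression_dataset("D", mat,
                           rep(c("disease", "control"), each = n),
                           "log2", "A")
  cl <- cluster_samples(ds, rownames(mat))
  expect_length(unique(cl$labels[1:n]), 1L)
  expect_length(unique(cl$labels[(n + 1):(2 * n)]), 1L)
  expect_length(cl$misclustered, 0L)

  flat <- matrix(rep(c(1, 2, 3), 4), nrow = 3,
                 dimnames = list(c("K1", "K2", "K3"), sprintf("S%d", 1:4)))
  dsf <- expression_dataset("F", flat,
                            rep(c("disease", "control"), each = 2),
                            "log2", "A")
  c1 <- cluster_samples(dsf, c("K1", "K2", "K3"))
  c2 <- cluster_samples(dsf, c("K1", "K2", "K3"))
  expect_identical(c1$labels, c2$labels)
  expect_error(cluster_samples(dsf, "K1"), ">= 2")
})

test_that("drug-masked disease samples co-cluster with controls", {
  fx <- generate_fixture(tiny_config(seed = 8))
  keys <- fx$truth$planted_key_genes
  for (d in seq_along(fx$datasets)) {
    cl <- cluster_samples(fx$datasets[[d]]$A, keys)
    expect_setequal(cl$misclustered, fx$truth$masked_samples[[d]])
  }
})

test_that("remove-and-rerun is the identity for an empty removal set", {
  fx <- generate_fixture(tiny_config(seed = 9))
  res <- run_cppin_pipeline(fx, overlap_samples = 0)
  rr <- remove_and_rerun(fx$datasets, character(), res$top$membership,
                         res$keys)
  expect_setequal(rr$keys, res$keys)
  expect_length(rr$additional, 0L)
})

test_that("removing masked samples surfaces therapy-sensitive genes", {
  fx <- generate_fixture(tiny_config(seed = 10, noise_sd = 0.05))
  res <- suppressWarnings(run_cppin_pipeline(fx, overlap_samples = 0))
  sens <- fx$truth$sensitive_genes
  # before removal the sensitive genes are diluted below the FC gate
  expect_false(any(sens %in% res$keys))
  removal <- stats::setNames(fx$truth$masked_samples,
                             vapply(fx$datasets, `[[`, "", "name"))
  rr <- remove_and_rerun(fx$datasets, removal, res$top$membership,
                         res$keys)
  expect_true(all(fx$truth$planted_key_genes %in% rr$keys))
  expect_true(all(sens %in% rr$additional))
})

test_that("datasets left with too few disease samples are dropped loudly", {
  fx <- generate_fixture(tiny_config(seed = 13))
  res <- run_cppin_pipeline(fx, overlap_samples = 0)
  all_disease <- names(fx$datasets[[1L]]$A$groups)[
    fx$datasets[[1L]]$A$groups == "disease"]
  removal <- stats::setNames(list(all_disease), fx$datasets[[1L]]$name)
  expect_warning(
    rr <- remove_and_rerun(fx$datasets, removal, res$top$membership,
                           res$keys),
    "dropped")
  expect_true(length(rr$keys) >= 0L)
})
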