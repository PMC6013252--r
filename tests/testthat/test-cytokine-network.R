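micro_spec <- function(cytokine = "CYTA", receptors = "R",
                       tf_name = "TFX", tf_genes = "T") {
  validate_signaling_spec(data.frame(
    cytokine = cytokine, receptors = receptors, tf_name = tf_name,
    tf_genes = tf_genes, stringsAsFactors = FALSE))
}

test_that("graph construction deduplicates and drops self-loops", {
  g <- build_graph(data.frame(a = c("A", "B", "A"), b = c("B", "A", "A")))
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)
  g0 <- build_graph(data.frame(a = character(), b = character()))
  expect_equal(igraph::vcount(g0), 0L)
})

test_that("shortest-path enumeration handles lines, cycles and edge cases", {
  g <- build_graph(data.frame(a = c("A", "B"), b = c("B", "C")))
  ps <- all_shortest_paths(g, "A", "C")
  expect_equal(ps$length, 2L)
  expect_equal(ps$paths, list(c("A", "B", "C")))

  cyc <- build_graph(data.frame(a = c("A", "B", "C", "D"),
                                b = c("B", "C", "D", "A")))
  ps2 <- all_shortest_paths(cyc, "A", "C")
  expect_equal(ps2$length, 2L)
  expect_setequal(vapply(ps2$paths, paste, "", collapse = "-"),
                  c("A-B-C", "A-D-C"))

  same <- all_shortest_paths(g, "B", "B")
  expect_equal(same$length, 0L)
  expect_equal(same$paths, list("B"))

  two <- build_graph(data.frame(a = c("A", "X"), b = c("B", "Y")))
  un <- all_shortest_paths(two, "A", "X")
  expect_true(is.infinite(un$length))
  expect_length(un$paths, 0L)
  expect_error(all_shortest_paths(g, "A", "ZZ"), "not in graph")
})

test_that("geodesic enumeration matches exhaustive simple-path search", {
  set.seed(7)
  for (rep in 1:30) {
    rg <- random_simple_graph(sample(5:10, 1L), runif(1, 0.2, 0.5))
    if (nrow(rg$edges) == 0L) next
    g <- build_graph(rg$edges, isolated = rg$nodes)
    adj <- oracle_adjlist(rg$nodes, rg$edges)
    pick <- sample(rg$nodes, 2L)
    got <- all_shortest_paths(g, pick[1L], pick[2L])
    exp <- oracle_all_shortest_paths(adj, pick[1L], pick[2L])
    expect_equal(got$length, exp$length)
    expect_setequal(vapply(got$paths, paste, "", collapse = "-"),
                    vapply(exp$paths, paste, "", collapse = "-"))
  }
})

test_that("receptor/TF pair expansion counts combinations per row", {
  spec <- micro_spec(receptors = "R1,R2", tf_genes = "T1,T2,T3")
  enum <- enumerate_receptor_tf_pairs(spec)
  expect_equal(enum$row_counts, 6L)
  expect_equal(enum$total, 6L)
  expect_equal(nrow(enum$pairs), 6L)
  expect_setequal(unique(enum$pairs$receptor), c("R1", "R2"))
})

test_that("intermediates are interior nodes minus spec endpoints", {
  spec <- micro_spec()
  ps1 <- structure(list(source = "R", target = "T", length = 2L,
                        paths = list(c("R", "X", "T"))), class = "path_set")
  out <- extract_intermediates(list(ps1), spec)
  expect_equal(out$intermediates, "X")
  expect_equal(unname(out$occurrence["X"]), 1L)

  ps2 <- structure(list(source = "R", target = "T", length = 1L,
                        paths = list(c("R", "T"))), class = "path_set")
  expect_length(extract_intermediates(list(ps2), spec)$intermediates, 0L)
  # occurrence counts geodesics, not pairs
  ps3 <- structure(list(source = "R", target = "T", length = 2L,
                        paths = list(c("R", "X", "T"), c("R", "Y", "T"))),
                   class = "path_set")
  out3 <- extract_intermediates(list(ps1, ps3), spec)
  expect_equal(unname(out3$occurrence[c("X", "Y")]), c(2L, 1L))
})

test_that("neighborhoods equal a brute-force edge-list scan", {
  star <- build_graph(data.frame(a = "HUB", b = c("L1", "L2", "L3")))
  expect_setequal(neighborhood_nodes(star, "HUB"), c("L1", "L2", "L3"))
  iso <- build_graph(data.frame(a = "A", b = "B"), isolated = "Z")
  expect_length(neighborhood_nodes(iso, "Z"), 0L)
  set.seed(11)
  for (rep in 1:10) {
    rg <- random_simple_graph(8, 0.35)
    if (nrow(rg$edges) == 0L) next
    g <- build_graph(rg$edges, isolated = rg$nodes)
    seeds <- sample(rg$nodes, 2L)
    scan <- unique(c(rg$edges$b[rg$edges$a %in% seeds],
                     rg$edges$a[rg$edges$b %in% seeds]))
    expect_setequal(neighborhood_nodes(g, seeds), scan)
  }
})

test_that("CPPIN assembly on the worked micro-example", {
  sppin <- build_graph(data.frame(a = c("R", "X", "X"),
                                  b = c("X", "T", "Y")))
  spec <- micro_spec()
  res <- build_cppin(sppin, spec)
  expect_setequal(igraph::V(res$graph)$name, c("CYTA", "R", "X", "T", "Y"))
  el <- igraph::as_edgelist(res$graph)
  got <- apply(el, 1L, function(e) paste(sort(e), collapse = "-"))
  expect_setequal(got, c("CYTA-R", "R-X", "T-X", "X-Y"))
  expect_setequal(res$node_roles[["X"]], "intermediate")
  expect_true("cytokine" %in% res$node_roles[["CYTA"]])
  expect_equal(res$pair_table$n_geodesics, 1)
  expect_equal(unname(res$intermediate_occurrence["X"]), 1L)
})

test_that("spec genes absent from the network are skipped, not fatal", {
  sppin <- build_graph(data.frame(a = "R", b = "T"))
  spec <- micro_spec(receptors = "R,RMISS", tf_genes = "T")
  res <- build_cppin(sppin, spec)
  expect_true("RMISS" %in% res$skip_report)
  expect_equal(res$pair_table$status,
               c("connected", "absent")[order(res$pair_table$receptor) ])
})

test_that("CPPIN is contained in SPPIN plus cytokine-receptor edges", {
  fx <- generate_fixture(tiny_config(seed = 4))
  res <- run_cppin_pipeline(fx, overlap_samples = 0)
  sp_el <- igraph::as_edgelist(res$sppin)
  sp_key <- paste(pmin(sp_el[, 1], sp_el[, 2]), pmax(sp_el[, 1], sp_el[, 2]))
  cp_el <- igraph::as_edgelist(res$cppin$graph)
  cp_key <- paste(pmin(cp_el[, 1], cp_el[, 2]), pmax(cp_el[, 1], cp_el[, 2]))
  cyt <- unique(fx$spec$cytokine)
  is_cyt_edge <- cp_el[, 1] %in% cyt | cp_el[, 2] %in% cyt
  expect_true(all(cp_key[!is_cyt_edge] %in% sp_key))
})

test_that("noiseless fixtures recover the planted chain interiors exactly", {
  fx <- generate_fixture(noiseless_config(seed = 6))
  res <- run_cppin_pipeline(fx, overlap_samples = 0)
  planted <- sort(unique(unlist(fx$truth$chain_interiors)))
  expect_setequal(names(res$cppin$intermediate_occurrence), planted)
})

test_that("densifying a graph never lengthens geodesics", {
  set.seed(21)
  rg <- random_simple_graph(9, 0.3)
  g1 <- build_graph(rg$edges, isolated = rg$nodes)
  extra <- data.frame(a = c("N01", "N02"), b = c("N05", "N09"))
  g2 <- build_graph(rbind(rg$edges, extra), isolated = rg$nodes)
  for (pair in list(c("N01", "N07"), c("N03", "N09"))) {
    d1 <- all_shortest_paths(g1, pair[1L], pair[2L])$length
    d2 <- all_shortest_paths(g2, pair[1L], pair[2L])$length
    expect_lte(d2, d1)
  }
})
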