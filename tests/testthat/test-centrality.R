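path3 <- function() build_graph(data.frame(a = c("A", "B"), b = c("B", "C")))

test_that("closed-form centralities: star, path, cycle, complete graph", {
  star <- build_graph(data.frame(a = "C0", b = c("L1", "L2", "L3", "L4")))
  cd <- degree_centrality(star)
  expect_equal(unname(cd["C0"]), 1.0)
  expect_equal(unname(cd["L1"]), 0.25)
  ce <- eigenvector_centrality(star)
  expect_equal(unname(ce["C0"]), 1.0)
  expect_equal(unname(ce[c("L1", "L4")]), c(0.5, 0.5), tolerance = 1e-8)

  p <- path3()
  cb <- betweenness_centrality(p)
  expect_equal(unname(cb[c("A", "B", "C")]), c(0, 1, 0))
  cc <- closeness_centrality(p)
  expect_equal(unname(cc["B"]), 1 / 2)
  expect_equal(unname(cc["A"]), 1 / 3)

  cyc <- build_graph(data.frame(a = c("A", "B", "C", "D"),
                                b = c("B", "C", "D", "A")))
  expect_equal(unname(betweenness_centrality(cyc)), rep(0.5, 4))

  k5 <- build_graph(as.data.frame(t(combn(paste0("K", 1:5), 2))))
  expect_equal(unname(degree_centrality(k5)), rep(1, 5))
  expect_equal(unname(closeness_centrality(k5)), rep(1 / 4, 5))
  expect_equal(unname(eigenvector_centrality(k5)), rep(1, 5),
               tolerance = 1e-8)
})

test_that("centralities match brute-force oracles on random graphs", {
  set.seed(31)
  for (rep in 1:25) {
    rg <- random_simple_graph(sample(6:12, 1L), runif(1, 0.2, 0.5))
    if (nrow(rg$edges) < 2L) next
    g <- build_graph(rg$edges, isolated = rg$nodes)
    ord <- igraph::V(g)$name
    expect_equal(degree_centrality(g),
                 oracle_degree_centrality(rg$nodes, rg$edges)[ord])
    expect_equal(betweenness_centrality(g),
                 oracle_betweenness(rg$nodes, rg$edges)[ord],
                 tolerance = 1e-10)
    expect_equal(closeness_centrality(g),
                 oracle_closeness(rg$nodes, rg$edges)[ord])
  }
})

test_that("eigenvector centrality matches dense eigendecomposition", {
  set.seed(33)
  for (rep in 1:10) {
    rg <- random_simple_graph(sample(10:50, 1L), runif(1, 0.1, 0.3))
    if (nrow(rg$edges) < 2L) next
    g <- build_graph(rg$edges, isolated = rg$nodes)
    comp <- igraph::components(g)
    # compare on the dominant component (other components decay to 0)
    big <- which.max(tapply(
      igraph::degree(g), comp$membership, function(d) max(sum(d), 0)))
    got <- eigenvector_centrality(g, tol = 1e-12)
    exp <- oracle_eigenvector(rg$nodes, rg$edges)
    keep <- names(got)[comp$membership == as.integer(big)]
    expect_equal(got[keep], exp[keep], tolerance = 1e-6)
  }
})

test_that("centralities are invariant under node relabeling", {
  set.seed(35)
  rg <- random_simple_graph(9, 0.35)
  g <- build_graph(rg$edges, isolated = rg$nodes)
  perm <- sample(rg$nodes)
  relab <- stats::setNames(perm, rg$nodes)
  edges2 <- data.frame(a = unname(relab[rg$edges$a]),
                       b = unname(relab[rg$edges$b]))
  g2 <- build_graph(edges2, isolated = perm)
  for (f in list(degree_centrality, betweenness_centrality,
                 closeness_centrality)) {
    v1 <- f(g); v2 <- f(g2)
    expect_equal(unname(v1[rg$nodes]), unname(v2[unname(relab[rg$nodes])]),
                 tolerance = 1e-10)
  }
})

test_that("adding an edge never decreases degree centrality of endpoints", {
  set.seed(37)
  rg <- random_simple_graph(8, 0.3)
  g <- build_graph(rg$edges, isolated = rg$nodes)
  cd1 <- degree_centrality(g)
  expect_true(all(cd1 >= 0 & cd1 <= 1))
  nonedge <- NULL
  for (a in rg$nodes) for (b in rg$nodes)
    if (a < b && !igraph::are_adjacent(g, a, b)) nonedge <- c(a, b)
  g2 <- build_graph(rbind(rg$edges,
                          data.frame(a = nonedge[1L], b = nonedge[2L])),
                    isolated = rg$nodes)
  cd2 <- degree_centrality(g2)
  expect_gte(cd2[nonedge[1L]], cd1[nonedge[1L]])
  expect_gte(cd2[nonedge[2L]], cd1[nonedge[2L]])
})

test_that("top-fraction extraction respects count and tie policy", {
  tab <- data.frame(node = sprintf("N%02d", 1:10),
                    degree = seq(1, 0.1, by = -0.1),
                    betweenness = 10:1, closeness = seq(0.9, 0, -0.1),
                    eigenvector = seq(1, 0.1, -0.1))
  top <- top_fraction(tab, 0.2)
  expect_setequal(top$per_measure$degree, c("N01", "N02"))
  expect_equal(unname(top$membership["N01"]), 4L)
  expect_equal(unname(top$membership["N10"]), 0L)

  # tie block straddling the cut: all members enter under include_ties
  tab$degree <- c(1, rep(0.5, 3), seq(0.4, 0.1, length.out = 6))
  t2 <- top_fraction(tab, 0.2)
  expect_setequal(t2$per_measure$degree, c("N01", "N02", "N03", "N04"))
  t3 <- top_fraction(tab, 0.2, tie_policy = "strict_count")
  expect_length(t3$per_measure$degree, 2L)
})

test_that("betweenness totals agree with aggregated geodesic interiors", {
  set.seed(39)
  for (rep in 1:5) {
    rg <- random_simple_graph(8, 0.4)
    if (nrow(rg$edges) < 3L) next
    g <- build_graph(rg$edges, isolated = rg$nodes)
    expect_equal(sum(betweenness_centrality(g)),
                 sum(oracle_betweenness(rg$nodes, rg$edges)),
                 tolerance = 1e-10)
  }
})
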