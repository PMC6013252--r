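test_that("generation is deterministic for a fixed seed", {
  f1 <- generate_fixture(tiny_config(seed = 14))
  f2 <- generate_fixture(tiny_config(seed = 14))
  expect_identical(f1$sources, f2$sources)
  expect_identical(f1$truth$planted_key_genes, f2$truth$planted_key_genes)
  expect_identical(f1$datasets[[2L]]$A$matrix, f2$datasets[[2L]]$A$matrix)
  f3 <- generate_fixture(tiny_config(seed = 15))
  expect_false(identical(f1$datasets[[1L]]$A$matrix,
                         f3$datasets[[1L]]$A$matrix))
})

test_that("written fixtures are byte-identical across repeated writes", {
  fx <- generate_fixture(tiny_config(seed = 16))
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_fixture(fx, d1)
  p2 <- write_fixture(generate_fixture(tiny_config(seed = 16)), d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), info = nm)
  }
})

test_that("the RNG stream split isolates the network from the datasets", {
  a <- generate_fixture(tiny_config(seed = 17))
  b <- generate_fixture(tiny_config(seed = 17, n_datasets = 2L,
                                    n_disease = c(10L, 12L),
                                    n_control = c(10L, 9L),
                                    masked_per_dataset = c(0L, 6L)))
  expect_identical(a$sources, b$sources)
  expect_identical(a$truth$planted_coexpressed_edges,
                   b$truth$planted_coexpressed_edges)
})

test_that("without noise, every emitted edge is planted signal", {
  fx <- generate_fixture(noiseless_config(seed = 18))
  planted <- paste(fx$truth$planted_coexpressed_edges$symbol_a,
                   fx$truth$planted_coexpressed_edges$symbol_b)
  for (s in fx$sources) {
    rec <- map_to_gene_symbols(s, fx$id_map)$records
    key <- paste(pmin(rec$symbol_a, rec$symbol_b),
                 pmax(rec$symbol_a, rec$symbol_b))
    expect_true(all(key %in% planted))
  }
})

test_that("duplicated emissions merge back to the distinct planted count", {
  fx <- generate_fixture(noiseless_config(seed = 19,
                                          duplicate_edge_frac = 0.2))
  mapped <- lapply(fx$sources, function(s)
    map_to_gene_symbols(s, fx$id_map)$records)
  ppi <- merge_interactions(mapped)
  expect_equal(nrow(ppi$edges),
               nrow(fx$truth$planted_coexpressed_edges))
  expect_gt(ppi$n_records_in, nrow(ppi$edges))  # duplicates were emitted
})

test_that("fixtures round-trip through disk", {
  fx <- generate_fixture(tiny_config(seed = 20))
  dir <- tempfile()
  write_fixture(fx, dir)
  back <- read_fixture(dir)
  expect_identical(names(back$sources), names(fx$sources))
  expect_equal(back$sources[[2L]]$id_a, fx$sources[[2L]]$id_a)
  expect_equal(back$id_map, fx$id_map)
  expect_equal(back$localization$whitelist, fx$localization$whitelist)
  expect_setequal(back$drug_targets, fx$drug_targets)
  expect_equal(back$spec, fx$spec)
  m0 <- fx$datasets[[1L]]$A$matrix
  m1 <- back$datasets[[1L]]$A$matrix
  expect_equal(m1[rownames(m0), colnames(m0)], m0, tolerance = 1e-9)
  expect_setequal(back$truth$planted_key_genes,
                  fx$truth$planted_key_genes)
})

test_that("an empty drug-target list is valid and yields the p = 1 policy", {
  fx <- generate_fixture(tiny_config(seed = 21))
  fx$drug_targets <- character()
  dir <- tempfile()
  write_fixture(fx, dir)
  back <- read_fixture(dir)
  expect_length(back$drug_targets, 0L)
  g <- build_graph(fx$truth$planted_coexpressed_edges)
  rr <- resample_null(g, 4, back$drug_targets, 0, n_samples = 50, seed = 1)
  expect_equal(rr$p_overlap, 1)
  expect_true(rr$empty_targets)
})

test_that("configurations whose scaffold cannot fit are rejected", {
  expect_error(generate_fixture(tiny_config(n_genes = 60L)),
               "does not fit")
  expect_error(synthetic_config(background_edge_prob = 1.2), "noise rates")
  expect_error(synthetic_config(chain_length_range = c(0, 2)),
               "chain_length_range")
  expect_error(tiny_config(masked_per_dataset = c(0L, 11L, 0L)),
               "unmasked")
})

test_that("planted co-expression reaches the threshold in some dataset", {
  hits <- c()
  for (s in 22:24) {
    fx <- generate_fixture(tiny_config(seed = s))
    edges <- fx$truth$planted_coexpressed_edges
    pass <- rep(FALSE, nrow(edges))
    for (dp in fx$datasets) {
      mat <- dp$A$matrix[, dp$A$groups == "disease", drop = FALSE]
      r <- vapply(seq_len(nrow(edges)), function(i)
        cor(mat[edges$symbol_a[i], ], mat[edges$symbol_b[i], ]), 0)
      pass <- pass | (r > 0.7)
    }
    hits <- c(hits, mean(pass))
  }
  expect_gte(mean(hits), 0.95)
})

test_that("planted DE genes pass the calling rule in their datasets", {
  rates <- c()
  for (s in 25:26) {
    fx <- generate_fixture(tiny_config(seed = s))
    keys <- fx$truth$planted_key_genes
    tab <- run_diffexpr(fx$datasets, keys)
    prof <- de_profile(tab)
    # evaluate where the planted effect is at most mildly diluted by
    # drug-masked samples (heavy masking is the therapy-effect mechanism)
    cfg <- fx$config
    mild <- cfg$masked_per_dataset <= cfg$n_disease / 3
    for (g in keys) {
      planted <- fx$truth$planted_de[[g]]
      planted_ds <- which(planted != "none" & mild)
      called <- prof$directions[g, planted_ds]
      rates <- c(rates, mean(called == planted[planted_ds]))
    }
  }
  expect_gte(mean(rates), 0.90)
})
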