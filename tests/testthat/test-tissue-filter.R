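mk_ppi <- function(a, b) {
  merge_interactions(data.frame(symbol_a = a, symbol_b = b, source = "s",
                                evidence = NA_character_,
                                stringsAsFactors = FALSE))
}

mk_dataset <- function(mat, n_disease, name = "D1", tag = "A") {
  groups <- rep(c("disease", "control"),
                c(n_disease, ncol(mat) - n_disease))
  colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  expression_dataset(name, mat, groups, "log2", tag)
}

test_that("localization keeps an edge only when both endpoints qualify", {
  ppi <- mk_ppi(c("A", "R"), c("B", "X"))
  loc <- localization_table(
    list(A = "cytoplasm", B = "nucleus", X = "plasma membrane"),
    whitelist = "R")
  out <- localization_filter(ppi, loc)
  expect_equal(nrow(out$ppi$edges), 1L)      # A-B dropped, R-X kept
  expect_equal(out$ppi$edges$symbol_a, "R")
  expect_equal(sort(out$g_list), c("R", "X"))
  expect_equal(out$n_dropped_edges, 1L)
})

test_that("whitelist growth is monotone for localization", {
  ppi <- mk_ppi(c("A", "C"), c("B", "D"))
  loc0 <- localization_table(list(A = "cytoplasm", B = "cytoplasm"))
  loc1 <- localization_table(list(A = "cytoplasm", B = "cytoplasm"),
                             whitelist = c("C", "D"))
  e0 <- localization_filter(ppi, loc0)$ppi$edges
  e1 <- localization_filter(ppi, loc1)$ppi$edges
  expect_true(all(paste(e0$symbol_a, e0$symbol_b) %in%
                    paste(e1$symbol_a, e1$symbol_b)))
  expect_equal(nrow(e1), 2L)
})

test_that("pearson_r matches the product-moment formula", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  x <- c(1, 2, 4, 5); y <- c(1, 3, 3, 6)
  n <- length(x)
  r_manual <- (sum(x * y) - sum(x) * sum(y) / n) /
    sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  expect_equal(pearson_r(x, y), r_manual)
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_r(1:3, 1:4), "length")
})

test_that("co-expression threshold is strict and signed", {
  # gene pair engineered so that r is known exactly from the data
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(1.2, 2.1, 2.8, 4.3, 4.9, 6.0)
  r_xy <- pearson_r(x, y)
  mat <- rbind(A = c(x, 0, 0), B = c(y, 0, 0), C = c(-x, 0, 0))
  ds <- mk_dataset(mat, 6)
  ppi <- mk_ppi(c("A", "A"), c("B", "C"))
  # threshold exactly at r: strict > drops the edge
  at <- coexpression_filter(ppi, list(ds),
                            coexpression_config(r_threshold = r_xy))
  expect_equal(nrow(at$ppi$edges), 0L)
  below <- coexpression_filter(ppi, list(ds),
                               coexpression_config(r_threshold = r_xy - 1e-9))
  expect_equal(nrow(below$ppi$edges), 1L)
  # A-C is perfectly anti-correlated: signed rule excludes it always
  expect_false("C" %in% below$ppi$edges$symbol_b)
})

test_that("datasets missing an endpoint contribute no evidence", {
  x <- seq(1, 6) + 0.1 * c(1, -1, 0, 1, -1, 0)
  mat1 <- rbind(A = x, B = x + 0.01 * seq(6))
  mat2 <- rbind(A = x)                       # B unmeasured here
  ds1 <- mk_dataset(mat1, 6, "D1")
  ds2 <- mk_dataset(mat2, 6, "D2")
  ppi <- mk_ppi("A", "B")
  out <- coexpression_filter(ppi, list(ds1, ds2), coexpression_config())
  expect_true(is.na(out$r_table$D2))
  expect_equal(out$r_table$n_pass, 1L)
  # requiring 2 supporting datasets now fails
  out2 <- coexpression_filter(ppi, list(ds1, ds2),
                              coexpression_config(min_datasets = 2))
  expect_equal(nrow(out2$ppi$edges), 0L)
})

test_that("raising the correlation threshold never adds edges", {
  fx <- generate_fixture(tiny_config(seed = 11))
  mapped <- lapply(fx$sources, function(s)
    map_to_gene_symbols(s, fx$id_map)$records)
  ppi <- localization_filter(merge_interactions(mapped),
                             fx$localization)$ppi
  ds <- lapply(fx$datasets, `[[`, "A")
  lo <- coexpression_filter(ppi, ds, coexpression_config(r_threshold = 0.5))
  hi <- coexpression_filter(ppi, ds, coexpression_config(r_threshold = 0.8))
  key <- function(e) paste(e$symbol_a, e$symbol_b)
  expect_true(all(key(hi$ppi$edges) %in% key(lo$ppi$edges)))
})

test_that("localization and co-expression filters commute", {
  fx <- generate_fixture(tiny_config(seed = 12))
  mapped <- lapply(fx$sources, function(s)
    map_to_gene_symbols(s, fx$id_map)$records)
  ppi <- merge_interactions(mapped)
  ds <- lapply(fx$datasets, `[[`, "A")
  cfg <- coexpression_config()
  a <- coexpression_filter(localization_filter(ppi, fx$localization)$ppi,
                           ds, cfg)$ppi$edges
  co_first <- coexpression_filter(ppi, ds, cfg)$ppi
  b <- localization_filter(co_first, fx$localization)$ppi$edges
  expect_equal(a[, c("symbol_a", "symbol_b")],
               b[, c("symbol_a", "symbol_b")])
})

test_that("noiseless fixtures retain exactly the planted co-expressed edges", {
  fx <- generate_fixture(noiseless_config(seed = 2))
  mapped <- lapply(fx$sources, function(s)
    map_to_gene_symbols(s, fx$id_map)$records)
  ppi <- localization_filter(merge_interactions(mapped),
                             fx$localization)$ppi
  out <- coexpression_filter(ppi, lapply(fx$datasets, `[[`, "A"),
                             coexpression_config())
  got <- paste(out$ppi$edges$symbol_a, out$ppi$edges$symbol_b)
  planted <- paste(fx$truth$planted_coexpressed_edges$symbol_a,
                   fx$truth$planted_coexpressed_edges$symbol_b)
  # all retained edges are planted, and nearly all planted survive
  expect_true(all(got %in% planted))
  expect_gte(mean(planted %in% got), 0.95)
})
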