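#' Configuration for the synthetic fixture generator
#'
#' The generator emulates the full input stack of the analysis: several
#' overlapping interaction "databases" in two identifier namespaces with
#' duplication/self-loop/unmappable-identifier noise, a subcellular
#' localization table with a whitelist, per-dataset expression matrices in
#' two normalization variants with planted group differences and planted
#' co-expression, a cytokine signaling spec, and a drug-target list — all
#' with recorded ground truth.
#'
#' The planted scaffold: each cytokine's receptor genes are connected to
#' transcription-factor subunit genes by signal-transduction chains whose
#' interiors are the planted intermediates. A subset of intermediates are
#' hubs: they carry `hub_leaves` interactor neighbors each and form an
#' interconnected core ring, making them central by construction; key-hub
#' genes additionally receive the planted differential-expression effect,
#' so they are the planted key molecules. `n_sensitive` extra hubs model
#' therapy-sensitive genes: their expression effect is diluted by
#' drug-masked disease samples (planted control-like profiles) and only
#' emerges after those samples are removed.
#'
#' @param n_genes total gene universe size.
#' @param n_sources number of mock interaction databases (alternating
#'   symbol / accession namespaces).
#' @param n_cytokines,n_tfs numbers of cytokines and transcription factors
#'   in the generated signaling spec.
#' @param chain_length_range inclusive range for the number of interior
#'   intermediates per planted receptor-to-subunit chain. The default
#'   c(1, 2) guarantees that every planted chain is a geodesic of the
#'   scaffold, so the planted intermediates are recovered exactly.
#' @param background_edge_prob probability of a background interaction for
#'   pairs with at least one endpoint outside the co-expressed scaffold.
#' @param n_datasets number of expression datasets.
#' @param n_disease,n_control per-dataset group sizes (recycled).
#' @param de_effect_log2 planted log2 fold-change magnitude for key genes.
#' @param sensitive_effect_log2 planted (smaller) effect for
#'   therapy-sensitive genes in drug-masked datasets.
#' @param noise_sd per-gene Gaussian noise SD (log2 scale).
#' @param coexpr_r_target target Pearson correlation of planted
#'   co-expressed pairs across disease samples.
#' @param unmapped_id_frac,duplicate_edge_frac,self_loop_frac noise rates.
#' @param n_hubs number of planted key hubs.
#' @param hub_leaves interactor neighbors per hub.
#' @param n_sensitive number of therapy-sensitive hubs.
#' @param masked_per_dataset drug-masked disease samples per dataset
#'   (recycled to `n_datasets`).
#' @param seed RNG seed; sub-streams are split per artifact (network,
#'   sources, localization, per-dataset expression) so e.g. changing
#'   `n_datasets` does not perturb the network.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 500L, n_sources = 6L,
                             n_cytokines = 12L, n_tfs = 8L,
                             chain_length_range = c(1L, 2L),
                             background_edge_prob = 0.004,
                             n_datasets = 5L,
                             n_disease = c(5L, 12L, 12L, 13L, 10L),
                             n_control = c(9L, 9L, 4L, 10L, 10L),
                             de_effect_log2 = 1.5,
                             sensitive_effect_log2 = 0.75,
                             noise_sd = 0.15,
                             coexpr_r_target = 0.9,
                             unmapped_id_frac = 0.05,
                             duplicate_edge_frac = 0.10,
                             self_loop_frac = 0.02,
                             n_hubs = 10L, hub_leaves = 12L,
                             n_sensitive = 2L,
                             masked_per_dataset = c(0L, 6L, 1L, 6L, 0L),
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_sources = as.integer(n_sources),
              n_cytokines = as.integer(n_cytokines), n_tfs = as.integer(n_tfs),
              chain_length_range = as.integer(chain_length_range),
              background_edge_prob = background_edge_prob,
              n_datasets = as.integer(n_datasets),
              n_disease = rep_len(as.integer(n_disease), n_datasets),
              n_control = rep_len(as.integer(n_control), n_datasets),
              de_effect_log2 = de_effect_log2,
              sensitive_effect_log2 = sensitive_effect_log2,
              noise_sd = noise_sd, coexpr_r_target = coexpr_r_target,
              unmapped_id_frac = unmapped_id_frac,
              duplicate_edge_frac = duplicate_edge_frac,
              self_loop_frac = self_loop_frac,
              n_hubs = as.integer(n_hubs), hub_leaves = as.integer(hub_leaves),
              n_sensitive = as.integer(n_sensitive),
              masked_per_dataset = rep_len(as.integer(masked_per_dataset),
                                           n_datasets),
              seed = as.integer(seed))
  probs <- c(cfg$background_edge_prob, cfg$unmapped_id_frac,
             cfg$duplicate_edge_frac, cfg$self_loop_frac)
  if (any(probs < 0 | probs > 1)) stop("noise rates must be in [0, 1]")
  if (cfg$coexpr_r_target <= 0 || cfg$coexpr_r_target >= 1)
    stop("coexpr_r_target must be in (0, 1)")
  if (length(cfg$chain_length_range) != 2L || cfg$chain_length_range[1L] < 1L ||
      diff(cfg$chain_length_range) < 0L)
    stop("chain_length_range must be an increasing range with min >= 1")
  if (cfg$n_sources < 2L) stop("need at least 2 sources")
  if (any(cfg$n_disease - cfg$masked_per_dataset < 2L) ||
      any(cfg$n_control < 2L))
    stop("each dataset needs >= 2 unmasked disease and >= 2 control samples")
  structure(cfg, class = "synthetic_config")
}

# Evaluate expr under a deterministic sub-stream of cfg's seed, restoring
# the caller's RNG state afterwards.
with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed((seed %% 1000000L) * 1000L + offset)
  expr
}

# Planted scaffold: spec rows, chains, hubs, ring, leaves. Network stream.
build_scaffold <- function(cfg) {
  n_hub_total <- cfg$n_hubs + cfg$n_sensitive
  cytokines <- sprintf("CYT%02d", seq_len(cfg$n_cytokines))
  n_rec <- ifelse(seq_len(cfg$n_cytokines) %% 2L == 1L, 2L, 1L)
  receptors <- sprintf("REC%02d", seq_len(sum(n_rec)))
  rec_of <- split(receptors, rep(seq_len(cfg$n_cytokines), n_rec))
  sub_counts <- rep_len(c(5L, 1L, 2L, 6L, 1L, 3L, 1L, 2L), cfg$n_tfs)
  subunits <- sprintf("SUB%02d", seq_len(sum(sub_counts)))
  sub_of <- split(subunits, rep(seq_len(cfg$n_tfs), sub_counts))
  tf_names <- sprintf("TFC%02d", seq_len(cfg$n_tfs))
  rows <- list()
  for (i in seq_len(cfg$n_cytokines)) {
    t1 <- ((i - 1L) %% cfg$n_tfs) + 1L
    t2 <- ((i + 1L) %% cfg$n_tfs) + 1L
    for (t in unique(c(t1, t2))) {
      rows[[length(rows) + 1L]] <- data.frame(
        cytokine = cytokines[i],
        receptors = paste(rec_of[[i]], collapse = ","),
        tf_name = tf_names[t],
        tf_genes = paste(sub_of[[t]], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  spec <- do.call(rbind, rows)
  prs <- enumerate_receptor_tf_pairs(spec)$pairs
  key <- paste(prs$receptor, prs$tf_gene)
  prs <- prs[!duplicated(key), , drop = FALSE]
  np <- nrow(prs)
  if (np < n_hub_total)
    stop("scaffold too small: ", np, " receptor/subunit pairs but ",
         n_hub_total, " hubs requested")
  hub_pairs <- unique(round(seq(1L, np, length.out = n_hub_total)))
  while (length(hub_pairs) < n_hub_total)
    hub_pairs <- sort(unique(c(hub_pairs, setdiff(seq_len(np), hub_pairs)[1L])))
  hubs <- sprintf("HUB%02d", seq_len(n_hub_total))
  edges <- list()
  interiors <- character()
  chain_interiors <- vector("list", np)
  n_int <- 0L
  for (j in seq_len(np)) {
    r <- prs$receptor[j]; s <- prs$tf_gene[j]
    hj <- match(j, hub_pairs)
    if (!is.na(hj)) {
      ints <- hubs[hj]
    } else {
      L <- sample(seq(cfg$chain_length_range[1L], cfg$chain_length_range[2L]),
                  1L)
      ints <- sprintf("INT%03d", n_int + seq_len(L))
      n_int <- n_int + L
    }
    chain_interiors[[j]] <- ints
    path <- c(r, ints, s)
    edges[[length(edges) + 1L]] <-
      cbind(path[-length(path)], path[-1L])
    interiors <- c(interiors, ints)
  }
  interiors <- unique(interiors)
  # hub core ring: interconnected signal transducers
  if (n_hub_total >= 3L) {
    ring <- cbind(hubs, hubs[c(seq_len(n_hub_total)[-1L], 1L)])
    edges[[length(edges) + 1L]] <- ring
  }
  leaves <- list()
  for (h in seq_len(n_hub_total)) {
    lv <- sprintf("NBR%02d_%02d", h, seq_len(cfg$hub_leaves))
    leaves[[h]] <- lv
    edges[[length(edges) + 1L]] <- cbind(hubs[h], lv)
  }
  edge_mat <- do.call(rbind, edges)
  module_edges <- data.frame(symbol_a = pmin(edge_mat[, 1L], edge_mat[, 2L]),
                             symbol_b = pmax(edge_mat[, 1L], edge_mat[, 2L]),
                             stringsAsFactors = FALSE)
  module_edges <- unique(module_edges)
  module_genes <- unique(c(receptors, subunits, interiors, unlist(leaves)))
  n_bg <- cfg$n_genes - length(module_genes)
  if (n_bg < 10L)
    stop("planted scaffold (", length(module_genes),
         " genes) does not fit in n_genes = ", cfg$n_genes)
  bg_genes <- sprintf("BGD%03d", seq_len(n_bg))
  list(spec = spec, pairs = prs, chain_interiors = chain_interiors,
       cytokines = cytokines, receptors = receptors, subunits = subunits,
       interiors = interiors, hubs = hubs,
       key_hubs = hubs[seq_len(cfg$n_hubs)],
       sensitive_hubs = if (cfg$n_sensitive > 0L)
         hubs[cfg$n_hubs + seq_len(cfg$n_sensitive)] else character(),
       leaves = leaves, module_edges = module_edges,
       module_genes = module_genes, bg_genes = bg_genes,
       genes = c(module_genes, bg_genes))
}

# Background edges: pairs with >= 1 endpoint outside the co-expressed
# module (background interactions exist but are not tissue co-expressed).
draw_background_edges <- function(cfg, sc) {
  nb <- length(sc$bg_genes); nm <- length(sc$module_genes)
  n_possible <- nb * (nb - 1) / 2 + nb * nm
  m <- stats::rbinom(1L, round(n_possible), cfg$background_edge_prob)
  if (m == 0L) return(sc$module_edges[0L, ])
  seen <- character()
  out <- vector("list", m)
  got <- 0L
  guard <- 0L
  while (got < m && guard < 50L * m) {
    guard <- guard + 1L
    a <- sample(sc$bg_genes, 1L)
    b <- sample(sc$genes, 1L)
    if (a == b) next
    lo <- min(a, b); hi <- max(a, b)
    k <- paste(lo, hi)
    if (k %in% seen) next
    seen <- c(seen, k)
    got <- got + 1L
    out[[got]] <- c(lo, hi)
  }
  em <- do.call(rbind, out[seq_len(got)])
  data.frame(symbol_a = em[, 1L], symbol_b = em[, 2L],
             stringsAsFactors = FALSE)
}

# Distribute edges over mock source databases, add duplicate / self-loop
# noise, and translate accession-namespace sources (with unmappable-id
# corruption). Every module edge is guaranteed one clean symbol-namespace
# emission so mapping noise cannot erase planted signal.
emit_sources <- function(cfg, sc, bg_edges) {
  src_names <- sprintf("DB%d", seq_len(cfg$n_sources))
  namespaces <- rep_len(c("symbol", "accession"), cfg$n_sources)
  sym_src <- which(namespaces == "symbol")
  acc_map <- stats::setNames(sprintf("ACC%05d", seq_along(sc$genes)),
                             sc$genes)
  evid <- c("Y2H", "coIP", "pulldown", "complex")
  recs <- vector("list", cfg$n_sources)
  add <- function(i, a, b) {
    recs[[i]][[length(recs[[i]]) + 1L]] <<- c(a, b)
  }
  for (i in seq_len(cfg$n_sources)) recs[[i]] <- list()
  all_edges <- rbind(sc$module_edges, bg_edges)
  n_mod <- nrow(sc$module_edges)
  for (e in seq_len(nrow(all_edges))) {
    a <- all_edges$symbol_a[e]; b <- all_edges$symbol_b[e]
    home <- if (e <= n_mod) sym_src[sample.int(length(sym_src), 1L)]
            else sample.int(cfg$n_sources, 1L)
    add(home, a, b)
    if (stats::runif(1L) < cfg$duplicate_edge_frac) {
      other <- sample.int(cfg$n_sources, 1L)
      # symmetric repeat half the time to exercise A-B/B-A collapsing
      if (stats::runif(1L) < 0.5) add(other, b, a) else add(other, a, b)
    }
  }
  sources <- vector("list", cfg$n_sources)
  for (i in seq_len(cfg$n_sources)) {
    em <- do.call(rbind, recs[[i]])
    if (is.null(em)) em <- matrix(character(), 0L, 2L)
    n_loops <- stats::rbinom(1L, nrow(em), cfg$self_loop_frac)
    if (n_loops > 0L) {
      g <- sample(sc$genes, n_loops, replace = TRUE)
      em <- rbind(em, cbind(g, g))
    }
    ida <- em[, 1L]; idb <- em[, 2L]
    if (namespaces[i] == "accession" && nrow(em) > 0L) {
      ida <- unname(acc_map[ida]); idb <- unname(acc_map[idb])
      corrupt <- function(ids) {
        hit <- stats::runif(length(ids)) < cfg$unmapped_id_frac
        ids[hit] <- sprintf("BAD%05d", sample.int(99999L, sum(hit),
                                                  replace = TRUE))
        ids
      }
      ida <- corrupt(ida); idb <- corrupt(idb)
    }
    nr <- length(ida)
    sources[[i]] <- data.frame(
      id_a = ida, id_b = idb,
      namespace = rep(namespaces[i], nr),
      source = rep(src_names[i], nr),
      evidence = if (nr > 0L) sample(evid, nr, replace = TRUE)
                 else character(),
      stringsAsFactors = FALSE)
  }
  names(sources) <- src_names
  list(sources = sources,
       id_map = stats::setNames(sc$genes, unname(acc_map)),
       per_source_emitted = vapply(sources, nrow, integer(1L)))
}

# Localization: module genes pass (annotation or whitelist); background
# genes get mixed compartments so the filter has something to drop.
build_localization <- function(cfg, sc) {
  ann <- list()
  wl_rec <- utils::head(sc$receptors, 2L)
  wl_sub <- sc$subunits[seq_along(sc$subunits) %% 2L == 0L]
  for (r in setdiff(sc$receptors, wl_rec)) ann[[r]] <- "plasma membrane"
  for (s in setdiff(sc$subunits, wl_sub)) ann[[s]] <- "cytoplasm"
  for (g in c(sc$interiors, unlist(sc$leaves)))
    ann[[g]] <- c("cytoplasm",
                  if (stats::runif(1L) < 0.2) "plasma membrane")
  comp_pool <- c("cytoplasm", "plasma membrane", "nucleus",
                 "mitochondrion", "extracellular")
  for (g in sc$bg_genes) {
    if (stats::runif(1L) < 0.6)
      ann[[g]] <- sample(comp_pool, sample(1:2, 1L))
  }
  localization_table(ann, whitelist = c(wl_rec, wl_sub))
}

# One dataset in two normalization variants. Co-expression is induced by a
# shared latent tissue factor over module genes, centered within each
# group so it cannot masquerade as differential expression.
build_dataset <- function(cfg, sc, truth, d) {
  nd <- cfg$n_disease[d]; nc <- cfg$n_control[d]
  samples <- c(sprintf("DS%d_RA%02d", d, seq_len(nd)),
               sprintf("DS%d_CT%02d", d, seq_len(nc)))
  groups <- stats::setNames(rep(c("disease", "control"), c(nd, nc)), samples)
  masked <- truth$masked_samples[[d]]
  genes <- sc$genes
  mu <- stats::runif(length(genes), 5, 10)
  lambda <- cfg$noise_sd * sqrt(cfg$coexpr_r_target /
                                  (1 - cfg$coexpr_r_target))
  f <- stats::rnorm(nd + nc)
  f[seq_len(nd)] <- f[seq_len(nd)] - mean(f[seq_len(nd)])
  f[nd + seq_len(nc)] <- f[nd + seq_len(nc)] - mean(f[nd + seq_len(nc)])
  A <- matrix(mu, length(genes), nd + nc, dimnames = list(genes, samples))
  is_module <- genes %in% sc$module_genes
  A[is_module, ] <- A[is_module, ] +
    matrix(lambda * f, sum(is_module), nd + nc, byrow = TRUE)
  unmasked_disease <- setdiff(samples[seq_len(nd)], masked)
  for (g in names(truth$planted_de)) {
    dir <- truth$planted_de[[g]][d]
    if (is.na(dir) || dir == "none") next
    eff <- if (g %in% sc$sensitive_hubs && cfg$masked_per_dataset[d] >= 2L)
      cfg$sensitive_effect_log2 else cfg$de_effect_log2
    A[g, unmasked_disease] <- A[g, unmasked_disease] +
      ifelse(dir == "up", eff, -eff)
  }
  A <- A + matrix(stats::rnorm(length(A), sd = cfg$noise_sd),
                  nrow(A), ncol(A))
  # variant B: affine monotone transform plus small independent noise,
  # mimicking a second normalization pipeline with concordant direction
  B <- 0.9 * A + 0.5 + matrix(stats::rnorm(length(A), sd = 0.05),
                              nrow(A), ncol(A))
  name <- sprintf("DS%d", d)
  list(name = name,
       A = expression_dataset(name, A, groups, "log2", "A"),
       B = expression_dataset(name, B, groups, "log2", "B"))
}

# Which datasets carry the planted effect, per gene class.
plant_de_truth <- function(cfg, sc) {
  planted <- list()
  dirs <- rep_len(c("up", "up", "down", "up", "down"), cfg$n_hubs)
  for (i in seq_len(cfg$n_hubs)) {
    planted[[sc$key_hubs[i]]] <-
      stats::setNames(rep(dirs[i], cfg$n_datasets), seq_len(cfg$n_datasets))
  }
  # therapy-sensitive hubs: full effect only in unmasked datasets, diluted
  # effect in heavily masked datasets, nothing in lightly masked ones
  for (g in sc$sensitive_hubs) {
    v <- rep("none", cfg$n_datasets)
    v[cfg$masked_per_dataset == 0L] <- "up"
    v[cfg$masked_per_dataset >= 2L] <- "up"
    planted[[g]] <- stats::setNames(v, seq_len(cfg$n_datasets))
  }
  # minor intermediates: sporadic DE (1-2 datasets) for pathway
  # directionality signal without key-molecule eligibility
  minor <- setdiff(sc$interiors, sc$hubs)
  minor <- utils::head(minor, min(12L, length(minor)))
  for (i in seq_along(minor)) {
    v <- rep("none", cfg$n_datasets)
    pick <- ((i - 1L) %% cfg$n_datasets) + 1L
    v[pick] <- if (i %% 2L == 0L) "up" else "down"
    if (cfg$n_datasets > 1L) {
      pick2 <- (pick %% cfg$n_datasets) + 1L
      v[pick2] <- v[pick]
    }
    planted[[minor[i]]] <- stats::setNames(v, seq_len(cfg$n_datasets))
  }
  planted
}

#' Generate a complete synthetic fixture with ground truth
#'
#' @param cfg a `synthetic_config`.
#' @return a `synthetic_fixture` list: `config`, `sources` (named list of
#'   interaction record data.frames), `id_map`, `localization`,
#'   `datasets` (list of `list(name, A, B)` expression variant pairs),
#'   `spec` (signaling spec), `drug_targets`, and `truth` (ground truth:
#'   planted key genes, per-gene planted DE directions, planted
#'   co-expressed edges, planted intermediates/hubs, masked samples,
#'   drug-target overlap bookkeeping, per-source emission counts).
#' @export
generate_fixture <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  sc <- with_stream(cfg$seed, 1L, build_scaffold(cfg))
  bg_edges <- with_stream(cfg$seed, 2L, draw_background_edges(cfg, sc))
  truth <- list()
  truth$masked_samples <- lapply(seq_len(cfg$n_datasets), function(d) {
    m <- cfg$masked_per_dataset[d]
    if (m == 0L) character() else sprintf("DS%d_RA%02d", d,
                                          cfg$n_disease[d] - seq_len(m) + 1L)
  })
  truth$planted_de <- plant_de_truth(cfg, sc)
  emission <- with_stream(cfg$seed, 3L, emit_sources(cfg, sc, bg_edges))
  localization <- with_stream(cfg$seed, 4L, build_localization(cfg, sc))
  datasets <- lapply(seq_len(cfg$n_datasets), function(d)
    with_stream(cfg$seed, 100L + d, build_dataset(cfg, sc, truth, d)))
  # drug targets: two planted keys, six hub interactors, four background
  drug_targets <- with_stream(cfg$seed, 5L, {
    first_leaves <- vapply(sc$leaves, `[[`, "", 1L)
    c(sc$key_hubs[1:2],
      utils::head(first_leaves[-(1:2)], 6L),
      sample(sc$bg_genes, 4L))
  })
  truth$planted_key_genes <- sc$key_hubs
  truth$sensitive_genes <- sc$sensitive_hubs
  truth$planted_coexpressed_edges <- sc$module_edges
  truth$planted_drug_targets <- drug_targets
  truth$planted_overlap_count <-
    length(intersect(drug_targets, truth$planted_key_genes))
  # direct-link bookkeeping by straight edge-list scan
  tgt <- unique(drug_targets)
  nontarget_keys <- setdiff(truth$planted_key_genes, tgt)
  adj <- rbind(as.matrix(sc$module_edges), as.matrix(bg_edges))
  has_link <- vapply(nontarget_keys, function(k) {
    nb <- c(adj[adj[, 1L] == k, 2L], adj[adj[, 2L] == k, 1L])
    any(nb %in% tgt)
  }, TRUE)
  truth$planted_direct_count <- sum(has_link)
  truth$intermediates <- sc$interiors
  truth$hubs <- sc$hubs
  truth$receptors <- sc$receptors
  truth$subunits <- sc$subunits
  truth$leaves <- sc$leaves
  truth$bg_genes <- sc$bg_genes
  truth$chain_interiors <- sc$chain_interiors
  truth$pairs <- sc$pairs
  truth$background_edges <- bg_edges
  truth$per_source_emitted <- emission$per_source_emitted
  structure(list(config = cfg, sources = emission$sources,
                 id_map = emission$id_map, localization = localization,
                 datasets = datasets, spec = sc$spec,
                 drug_targets = drug_targets, truth = truth),
            class = "synthetic_fixture")
}

#' @export
print.synthetic_fixture <- function(x, ...) {
  cat(sprintf("Synthetic fixture (seed %d): %d genes, %d sources, %d datasets, %d planted keys\n",
              x$config$seed, x$config$n_genes, length(x$sources),
              length(x$datasets), length(x$truth$planted_key_genes)))
  invisible(x)
}

#' Write a fixture to disk in the dialects the pipeline consumes
#'
#' @param fixture `synthetic_fixture`.
#' @param dir output directory (created if needed).
#' @return named character vector of written file paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wt <- function(df, file) {
    p <- file.path(dir, file)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[file] <<- p
  }
  for (nm in names(fixture$sources)) {
    src <- fixture$sources[[nm]]
    ns <- if (nrow(src) > 0L) src$namespace[1L] else "symbol"
    wt(src[, c("id_a", "id_b", "evidence")],
       sprintf("source_%s_%s.tsv", nm, ns))
  }
  wt(data.frame(identifier = names(fixture$id_map),
                symbol = unname(fixture$id_map)), "id_map.tsv")
  loc <- fixture$localization
  wt(data.frame(symbol = names(loc$annotations),
                compartments = vapply(loc$annotations, paste,
                                      "", collapse = ",")),
     "localization.tsv")
  p <- file.path(dir, "whitelist.txt")
  writeLines(loc$whitelist, p)
  paths["whitelist.txt"] <- p
  num <- function(m) {
    out <- data.frame(gene = rownames(m), format(m, digits = 12L,
                                                 trim = TRUE),
                      check.names = FALSE, stringsAsFactors = FALSE)
    out
  }
  for (dp in fixture$datasets) {
    wt(num(dp$A$matrix), sprintf("expr_%s_A.tsv", dp$name))
    wt(num(dp$B$matrix), sprintf("expr_%s_B.tsv", dp$name))
    wt(data.frame(sample_id = names(dp$A$groups), group = dp$A$groups),
       sprintf("annot_%s.tsv", dp$name))
  }
  wt(fixture$spec, "signaling_spec.tsv")
  wt(data.frame(target = fixture$drug_targets), "drug_targets.tsv")
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(fixture$truth, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths["ground_truth.json"] <- p
  invisible(paths)
}

#' Read a written fixture back into memory
#'
#' @param dir directory written by [write_fixture()].
#' @return a `synthetic_fixture` without `config` (the on-disk form does
#'   not carry the generator configuration).
#' @export
read_fixture <- function(dir) {
  src_files <- list.files(dir, "^source_.*\\.tsv$", full.names = TRUE)
  sources <- list()
  for (f in src_files) {
    base <- sub("\\.tsv$", "", basename(f))
    parts <- strsplit(base, "_", fixed = TRUE)[[1L]]
    nm <- parts[2L]; ns <- parts[3L]
    tab <- read.delim(f, stringsAsFactors = FALSE,
                      colClasses = "character")
    sources[[nm]] <- data.frame(id_a = tab$id_a, id_b = tab$id_b,
                                namespace = ns, source = nm,
                                evidence = tab$evidence,
                                stringsAsFactors = FALSE)
  }
  idt <- read.delim(file.path(dir, "id_map.tsv"), stringsAsFactors = FALSE)
  id_map <- stats::setNames(idt$symbol, idt$identifier)
  localization <- read_localization_table(
    file.path(dir, "localization.tsv"), file.path(dir, "whitelist.txt"))
  annot_files <- list.files(dir, "^annot_.*\\.tsv$", full.names = TRUE)
  datasets <- lapply(annot_files, function(af) {
    nm <- sub("^annot_(.*)\\.tsv$", "\\1", basename(af))
    list(name = nm,
         A = read_expression_dataset(nm, file.path(dir,
               sprintf("expr_%s_A.tsv", nm)), af, "log2", "A"),
         B = read_expression_dataset(nm, file.path(dir,
               sprintf("expr_%s_B.tsv", nm)), af, "log2", "B"))
  })
  spec <- read_signaling_spec(file.path(dir, "signaling_spec.tsv"))
  targets <- read.delim(file.path(dir, "drug_targets.tsv"),
                        stringsAsFactors = FALSE)$target
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  structure(list(config = NULL, sources = sources, id_map = id_map,
                 localization = localization, datasets = datasets,
                 spec = spec, drug_targets = as.character(targets %||%
                                                            character()),
                 truth = truth),
            class = "synthetic_fixture")
}
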