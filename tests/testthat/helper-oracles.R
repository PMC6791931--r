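# Independent brute-force oracles and random-fixture generators. These are
# deliberately written as plain loops over first definitions, separate from
# the package's vectorized implementations.

# CCC oracle: enumerate every sample's allele pairs explicitly, accumulate
# the 2x2 allele co-occurrence table, then score each cell
# (9/2) f_rs (1 - 2/3 f_r)(1 - 2/3 f_s) and take the maximum.
oracle_ccc <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) return(NA_real_)
  tab <- matrix(0, 2, 2)  # rows: allele of a (ref=1, alt=2); cols: allele of b
  count_a <- c(0, 0); count_b <- c(0, 0)
  for (k in seq_len(n)) {
    alleles_a <- c(rep(0, 2 - a[k]), rep(1, a[k]))
    alleles_b <- c(rep(0, 2 - b[k]), rep(1, b[k]))
    for (x in alleles_a) {
      count_a[x + 1] <- count_a[x + 1] + 1
      for (y in alleles_b) tab[x + 1, y + 1] <- tab[x + 1, y + 1] + 1
    }
    for (y in alleles_b) count_b[y + 1] <- count_b[y + 1] + 1
  }
  f_a <- count_a / (2 * n)
  f_b <- count_b / (2 * n)
  best <- 0
  for (r in 1:2) {
    for (s in 1:2) {
      f_rs <- tab[r, s] / (4 * n)
      val <- 4.5 * f_rs * (1 - (2 / 3) * f_a[r]) * (1 - (2 / 3) * f_b[s])
      if (val > best) best <- val
    }
  }
  min(best, 1)
}

# All-pairs Spearman edge oracle: per-pair stats::cor, simple double loop.
oracle_correlation_edges <- function(m, threshold) {
  ids <- rownames(m)
  out <- list()
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      r <- suppressWarnings(stats::cor(m[i, ], m[j, ], method = "spearman"))
      if (!is.na(r) && abs(r) >= threshold) {
        a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
        out[[length(out) + 1]] <- data.frame(node_a = a, node_b = b, rho = r)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(node_a = character(), node_b = character(), rho = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$node_a, res$node_b), , drop = FALSE]
}

# Per-gene breadth/depth oracle: scan each layer's edge list per gene.
oracle_scores <- function(one_hops, anchor_ids, universe) {
  layers <- vapply(one_hops, function(x) unique(x$layer)[1], character(1))
  genes <- sort(setdiff(universe[!startsWith(universe, "met:")], anchor_ids))
  res <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (ly in layers) res[[paste0("depth_", ly)]] <- 0L
  for (k in seq_along(one_hops)) {
    oh <- one_hops[[k]]
    for (g in genes) {
      partners <- character()
      for (e in seq_len(nrow(oh))) {
        a <- oh$node_a[e]; b <- oh$node_b[e]
        if (a == g && b %in% anchor_ids) partners <- c(partners, b)
        if (b == g && a %in% anchor_ids) partners <- c(partners, a)
      }
      res[res$gene == g, paste0("depth_", layers[k])] <- length(unique(partners))
    }
  }
  dm <- as.matrix(res[paste0("depth_", layers)])
  res$breadth <- as.integer(rowSums(dm > 0))
  res$depth_total <- as.integer(rowSums(dm))
  cometh <- if ("depth_comethylation" %in% colnames(res)) res$depth_comethylation else 0L
  res$depth_minus_cometh <- res$depth_total - cometh
  res
}

# Upper-tail hypergeometric oracle by explicit summation of the pmf.
oracle_hyper_upper <- function(k, K, N, n) {
  total <- 0
  for (j in k:min(K, n)) {
    total <- total + choose(K, j) * choose(N - K, n - j) / choose(N, n)
  }
  total
}

# Random multilayer 1-hop fixture: genes, a few anchors (genes + metabolites),
# random anchor-incident edges per layer. Returns list(one_hops, anchors,
# universe).
random_multilayer <- function(n_genes = 100, n_layers = 6, n_anchor = 8,
                              n_met = 4, mean_edges = 60, seed = 1) {
  withr::with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    anchor_genes <- sample(genes, n_anchor)
    mets <- paste0("met:M", seq_len(n_met))
    anchors <- loescore::anchor_set(anchor_genes, sub("^met:", "", mets))
    layer_names <- c("coexpression", "comethylation", "snp_correlation",
                     "gwas_traditional", "gwas_rare", "eqtn")[seq_len(n_layers)]
    one_hops <- lapply(layer_names, function(ly) {
      n_e <- stats::rpois(1, mean_edges) + 5L
      if (ly %in% c("gwas_traditional", "gwas_rare")) {
        ends_a <- sample(genes, n_e, replace = TRUE)
        ends_b <- sample(mets, n_e, replace = TRUE)
      } else {
        ends_a <- sample(genes, n_e, replace = TRUE)
        ends_b <- sample(c(genes, anchor_genes), n_e, replace = TRUE)
      }
      keep <- ends_a != ends_b
      ed <- unique(data.frame(
        node_a = pmin(ends_a[keep], ends_b[keep]),
        node_b = pmax(ends_a[keep], ends_b[keep])))
      ed$weight <- stats::runif(nrow(ed), -1, 1)
      net <- loescore::loe_network(ed, layer = ly)
      suppressMessages(loescore::extract_one_hop(net, anchors))
    })
    list(one_hops = one_hops, anchors = anchors,
         universe = c(genes, mets),
         anchor_ids = anchor_nodes(anchors))
  })
}

# Compact planted design + config for fast replicate-world tests.
small_world_config <- function() {
  design <- tibble::tibble(
    cx = c(2L, 1L, 1L, 0L, 2L),
    cm = c(1L, 1L, 0L, 2L, 1L),
    sc = c(1L, 0L, 1L, 1L, 0L),
    gt = c(1L, 0L, 1L, 0L, 1L),
    gr = c(0L, 1L, 0L, 1L, 0L))
  loescore::loe_sim_config(
    n_genes = 200, n_anchor_genes = 10, n_metabolites = 8,
    n_anchor_metabolites = 4, n_samples_geno = 60, n_background_snps = 15,
    n_background_assoc = 40, n_background_terms = 3,
    background_term_size = 25, planted = design)
}

# One-hop layer networks of a simulated world, as the pipeline would build
# them (in memory, no files).
world_one_hops <- function(world) {
  cfg <- world$config
  layers <- list(
    coexpression = suppressMessages(
      build_correlation_layer(world$expression, cfg$coexpr_threshold,
                              "coexpression")),
    comethylation = suppressMessages(
      build_correlation_layer(world$methylation, cfg$cometh_threshold,
                              "comethylation")),
    snp_correlation = build_snp_correlation_layer(
      maf_filter(world$genotypes, min_maf = 0.01), world$gene_models,
      ccc_min = cfg$ccc_min, min_dist_bp = cfg$min_dist_bp),
    gwas_traditional = suppressMessages(build_association_layer(
      world$associations, world$gene_models, world$genotypes$meta,
      flank_bp = 0, layer_tag = "gwas_traditional", q_max = cfg$fdr_q)),
    gwas_rare = suppressMessages(build_association_layer(
      world$associations, world$gene_models, world$genotypes$meta,
      flank_bp = 2000, layer_tag = "gwas_rare", q_max = cfg$fdr_q)))
  suppressMessages(lapply(layers, extract_one_hop, anchors = world$anchors))
}
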