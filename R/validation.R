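# The two randomization-based validation procedures -- shuffled-data
# correlation comparison and GO-functional-network intersect scoring against
# label-randomized LOE networks -- plus hypergeometric GO enrichment.

#' Shuffle an omics matrix within rows
#'
#' Independently permutes each feature's values across samples, preserving
#' every row's value multiset exactly while destroying sample associations.
#'
#' @param m Feature x sample matrix.
#' @param seed Integer seed for reproducibility (optional).
#' @return Shuffled matrix with the same dimnames.
#' @export
shuffle_within_rows <- function(m, seed = NULL) {
  assert_matrix(m)
  if (ncol(m) == 1) return(m)
  with_seed_opt(seed, {
    out <- t(apply(m, 1, function(r) r[sample.int(length(r))]))
    dimnames(out) <- dimnames(m)
    out
  })
}

#' Subsample Spearman correlations from random gene pairs
#'
#' Draws `n` distinct unordered feature pairs uniformly (without
#' replacement by default) and returns their Spearman correlations.
#' Zero-variance features are excluded before pairing.
#'
#' @param m Feature x sample matrix with at least 2 usable rows.
#' @param n Number of correlation values to draw.
#' @param seed Integer seed (optional).
#' @param replace Sample pairs with replacement (then any `n` is allowed).
#' @return Numeric vector of `n` Spearman rho values.
#' @export
subsample_correlations <- function(m, n, seed = NULL, replace = FALSE) {
  assert_matrix(m)
  constant <- apply(m, 1, function(x) length(unique(x)) == 1)
  m <- m[!constant, , drop = FALSE]
  r <- nrow(m)
  if (r < 2) abort("need at least 2 non-constant features")
  n_pairs <- r * (r - 1) / 2
  if (!replace && n > n_pairs) {
    abort(sprintf("n = %d exceeds the %d distinct pairs; use replace = TRUE", n, n_pairs))
  }
  ranks <- t(apply(m, 1, rank))
  z <- ranks - rowMeans(ranks)
  z <- z / sqrt(rowSums(z^2))
  with_seed_opt(seed, {
    k <- sample.int(n_pairs, n, replace = replace)
    # unrank k -> (i, j), i < j, in the upper-triangle column-major order;
    # the floating-point inverse is corrected by one step where needed
    j <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
    i <- k - (j - 1) * (j - 2) / 2
    low <- i < 1
    j[low] <- j[low] - 1
    i[low] <- k[low] - (j[low] - 1) * (j[low] - 2) / 2
    high <- i > j - 1
    j[high] <- j[high] + 1
    i[high] <- k[high] - (j[high] - 1) * (j[high] - 2) / 2
    unname(rowSums(z[i, , drop = FALSE] * z[j, , drop = FALSE]))
  })
}

#' Wilcoxon rank-sum comparison of two correlation pools
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum test; exact enumeration when the
#' smaller sample has at most 8 values and no ties are present, normal
#' approximation (with continuity correction) otherwise.
#'
#' @param observed,null Non-empty numeric vectors.
#' @return List with `statistic` (W) and `p_value`.
#' @export
#' @examples
#' ranksum_compare(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
ranksum_compare <- function(observed, null) {
  stopifnot(length(observed) > 0, length(null) > 0)
  exact <- min(length(observed), length(null)) <= 8 &&
    !anyDuplicated(c(observed, null))
  ht <- suppressWarnings(
    stats::wilcox.test(observed, null, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Shuffle-based validation of a correlation layer
#'
#' Generates `n_shuffles` within-row shuffled copies of the matrix, pools
#' `n_subsample` random Spearman correlations from each, draws a matching
#' observed pool, and compares the two distributions with the rank-sum test.
#' Also reports the fraction of correlations at or above the layer
#' threshold in each pool.
#'
#' @param m Feature x sample matrix.
#' @param threshold Layer threshold used for the tail-fraction comparison.
#' @param n_shuffles Number of shuffled datasets (default 100).
#' @param n_subsample Correlations drawn per dataset (default 100000,
#'   capped at the number of distinct pairs).
#' @param seed Integer seed.
#' @return Object of class `loe_shuffle_validation`: observed/shuffled
#'   pools, rank-sum statistic and p-value, and the supra-threshold
#'   fractions.
#' @export
validate_shuffle <- function(m, threshold = 0.85, n_shuffles = 100,
                             n_subsample = 100000, seed = 1) {
  assert_matrix(m)
  r <- nrow(m)
  n_pairs <- r * (r - 1) / 2
  n_sub <- min(n_subsample, n_pairs)
  shuffled <- unlist(lapply(seq_len(n_shuffles), function(b) {
    ms <- shuffle_within_rows(m, seed = derive_seed(seed, paste0("shuffle", b)))
    subsample_correlations(ms, n_sub, seed = derive_seed(seed, paste0("sub", b)))
  }))
  n_obs <- min(n_shuffles * n_sub, n_pairs)
  observed <- subsample_correlations(m, n_obs, seed = derive_seed(seed, "obs"))
  rs <- ranksum_compare(observed, shuffled)
  structure(list(observed = observed, shuffled = shuffled,
                 statistic = rs$statistic, p_value = rs$p_value,
                 threshold = threshold,
                 frac_observed = mean(abs(observed) >= threshold),
                 frac_shuffled = mean(abs(shuffled) >= threshold),
                 n_shuffles = n_shuffles, n_subsample = n_sub, seed = seed),
            class = "loe_shuffle_validation")
}

#' Build a GO-term functional network
#'
#' Connects every pair of genes sharing a GO term, with edge weight
#' `1 / (term gene count)` so rarer (more specific) terms carry more
#' functional value; terms annotated to more than `max_term_size` genes are
#' dropped to avoid a dense generic-function network. Pairs sharing several
#' terms keep only the highest-scoring edge (ties broken by term id) and
#' record the winning term.
#'
#' @param ann Annotation tibble `gene`, `term`.
#' @param max_term_size Maximum term size (default 1000).
#' @return A tibble of class `go_network` with `node_a`, `node_b`,
#'   `weight`, `term`.
#' @export
build_go_network <- function(ann, max_term_size = 1000) {
  ann <- distinct(as_tibble(ann)[c("gene", "term")])
  if (nrow(ann) == 0) abort("empty annotation")
  sizes <- count(ann, .data$term, name = "size")
  keep <- filter(sizes, .data$size <= max_term_size, .data$size >= 2)
  ann <- inner_join(ann, keep, by = "term")
  edges <- inner_join(ann, ann, by = "term", suffix = c("_a", "_b"),
                      relationship = "many-to-many") |>
    filter(.data$gene_a < .data$gene_b) |>
    mutate(weight = 1 / .data$size_a) |>
    arrange(.data$gene_a, .data$gene_b, desc(.data$weight), .data$term) |>
    distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) |>
    select(node_a = "gene_a", node_b = "gene_b", "weight", "term")
  class(edges) <- c("go_network", class(edges))
  edges
}

#' Randomize the neighbor labels of a 1-hop network
#'
#' Holds anchor nodes and the whole edge structure constant and replaces
#' each distinct non-anchor neighbor label with a distinct gene drawn
#' uniformly without replacement from `universe` minus the anchors. Node
#' count, edge count and per-anchor degree are all preserved.
#'
#' @param oh A 1-hop network from [extract_one_hop()].
#' @param universe Character vector of gene ids to draw replacements from.
#' @param seed Integer seed (optional).
#' @param anchors Anchor nodes to exclude from the replacement pool in
#'   addition to the network's own anchors (an [anchor_set()] or character
#'   vector); pass the full anchor set so anchors absent from this layer
#'   cannot be drawn as replacements.
#' @return The relabeled 1-hop network.
#' @export
randomize_one_hop <- function(oh, universe, seed = NULL, anchors = NULL) {
  own <- attr(oh, "anchors") %||% character()
  extra <- if (inherits(anchors, "anchor_set")) anchor_nodes(anchors)
           else anchors %||% character()
  anchors <- union(own, extra)
  neighbors <- attr(oh, "neighbors") %||%
    setdiff(unique(c(oh$node_a, oh$node_b)), anchors)
  if (length(neighbors) == 0) return(oh)
  pool <- setdiff(universe, anchors)
  if (length(pool) < length(neighbors)) {
    abort("universe too small to relabel all neighbors distinctly")
  }
  repl <- with_seed_opt(seed, sample(pool, length(neighbors)))
  map <- setNames(repl, neighbors)
  relabel <- function(x) ifelse(x %in% neighbors, unname(map[x]), x)
  edges <- as_tibble(oh)
  edges$node_a <- relabel(edges$node_a)
  edges$node_b <- relabel(edges$node_b)
  out <- loe_network(edges)
  attr(out, "anchors") <- anchors
  attr(out, "neighbors") <- unname(map)
  class(out) <- unique(c("one_hop", class(out)))
  out
}

#' GO intersect score of a gene network
#'
#' Sums the GO-network edge weights over unordered gene pairs that are also
#' edges of the given network. Each shared pair counts once regardless of
#' how many layers contribute it; metabolite nodes are ignored.
#'
#' @param net An `loe_network` (e.g. a merged LOE network).
#' @param go A `go_network` from [build_go_network()].
#' @param include_anchor_pairs If `FALSE`, pairs where both genes belong to
#'   `anchors` are excluded from the score.
#' @param anchors Optional anchor node ids (used only when
#'   `include_anchor_pairs = FALSE`).
#' @return The intersect score (non-negative real).
#' @export
intersect_score <- function(net, go, include_anchor_pairs = TRUE,
                            anchors = character()) {
  pairs <- as_tibble(net) |>
    filter(node_kind(.data$node_a) == "gene",
           node_kind(.data$node_b) == "gene") |>
    distinct(.data$node_a, .data$node_b)
  if (!include_anchor_pairs) {
    pairs <- filter(pairs, !(.data$node_a %in% anchors & .data$node_b %in% anchors))
  }
  shared <- inner_join(pairs, as_tibble(go), by = c("node_a", "node_b"))
  sum(shared$weight)
}

#' Summarize an observed statistic against a randomized null
#'
#' @param observed Observed statistic.
#' @param null_scores Numeric vector of statistics from randomized inputs.
#' @return Object of class `loe_null`: observed value, null summary
#'   (min/max/mean), number of randomizations, and the add-one empirical
#'   exceedance p-value `(1 + #\{null >= observed\}) / (n + 1)`.
#' @export
null_validation <- function(observed, null_scores) {
  stopifnot(length(null_scores) >= 1)
  structure(list(observed = observed, null = null_scores,
                 n = length(null_scores),
                 null_min = min(null_scores), null_max = max(null_scores),
                 null_mean = mean(null_scores),
                 p_value = (1 + sum(null_scores >= observed)) /
                   (length(null_scores) + 1)),
            class = "loe_null")
}

#' @export
print.loe_null <- function(x, ...) {
  cat(sprintf(paste0("Null-distribution validation: observed = %.4f, ",
                     "null range [%.4f, %.4f] (n = %d), p = %.4g\n"),
              x$observed, x$null_min, x$null_max, x$n, x$p_value))
  invisible(x)
}

# Lean vector-based replicate of score -> threshold -> merge -> intersect,
# used inside the randomization loop (the tibble pipeline is too slow for
# hundreds of replicates). loe_go_pipeline_score() is pinned against the
# regular path in the test suite.
fast_layer_edges <- function(one_hops) {
  lapply(one_hops, function(oh) {
    list(a = oh$node_a, b = oh$node_b, layer = unique(oh$layer)[1],
         neighbors = attr(oh, "neighbors") %||% character())
  })
}

fast_score_intersect <- function(layers, a_nodes, go_key, go_w,
                                 min_breadth, require_gwas) {
  gene_all <- character(); layer_all <- integer(); partner_all <- character()
  for (k in seq_along(layers)) {
    ed <- layers[[k]]
    a_in <- ed$a %in% a_nodes
    b_in <- ed$b %in% a_nodes
    g <- c(ed$a[b_in & !a_in], ed$b[a_in & !b_in])
    p <- c(ed$b[b_in & !a_in], ed$a[a_in & !b_in])
    keep <- !startsWith(g, "met:")
    gene_all <- c(gene_all, g[keep])
    layer_all <- c(layer_all, rep.int(k, sum(keep)))
    partner_all <- c(partner_all, p[keep])
  }
  high <- character()
  if (length(gene_all) > 0) {
    dup <- duplicated(paste(gene_all, layer_all, partner_all, sep = "\r"))
    gene_all <- gene_all[!dup]; layer_all <- layer_all[!dup]
    gl <- paste(gene_all, layer_all, sep = "\r")
    first <- !duplicated(gl)
    breadth <- table(gene_all[first])
    gwas_idx <- which(vapply(layers, function(x)
      x$layer %in% c("gwas_traditional", "gwas_rare"), logical(1)))
    gwas_cnt <- table(gene_all[layer_all %in% gwas_idx])
    genes <- names(breadth)
    gw <- as.integer(gwas_cnt[genes]); gw[is.na(gw)] <- 0L
    high <- genes[breadth >= min_breadth & (!require_gwas | gw >= 1)]
  }
  allowed <- c(a_nodes, high)
  keys <- character()
  for (ed in layers) {
    keep <- ed$a %in% allowed & ed$b %in% allowed &
      !startsWith(ed$a, "met:") & !startsWith(ed$b, "met:")
    if (any(keep)) {
      keys <- c(keys, paste(ed$a[keep], ed$b[keep], sep = "\r"))
    }
  }
  keys <- unique(keys)
  sum(go_w[stats::na.omit(match(keys, go_key))])
}

# Score one randomized or observed layer set through the fast path.
loe_go_pipeline_score <- function(one_hops, anchors, go, min_breadth = 3,
                                  require_gwas = TRUE) {
  layers <- fast_layer_edges(one_hops)
  fast_score_intersect(layers, anchor_nodes(anchors),
                       paste(go$node_a, go$node_b, sep = "\r"), go$weight,
                       min_breadth, require_gwas)
}

#' GO-functional validation of an LOE network
#'
#' Scores the observed 1-hop layers (LOE scoring, thresholding, merging,
#' then GO intersect score) and compares against `n_random` sets of
#' label-randomized layers processed identically: each replicate randomizes
#' the neighbor labels of every layer, re-scores, re-thresholds, re-merges
#' and re-intersects.
#'
#' @param one_hops List of 1-hop `loe_network`s (one per layer).
#' @param anchors An [anchor_set()].
#' @param go A `go_network`.
#' @param universe Gene ids replacements are drawn from.
#' @param n_random Number of randomized network sets (default 100).
#' @param min_breadth,require_gwas Passed to [threshold_and_merge()].
#' @param seed Integer seed.
#' @return An `loe_null` object with extra elements `observed_network`
#'   (the observed merged network) and `high_loe`.
#' @export
validate_go_network <- function(one_hops, anchors, go, universe,
                                n_random = 100, min_breadth = 3,
                                require_gwas = TRUE, seed = 1) {
  score_merge <- function(ohs) {
    sc <- compute_loe_scores(ohs, anchors)
    threshold_and_merge(ohs, sc, min_breadth = min_breadth,
                        require_gwas = require_gwas)
  }
  obs_merge <- score_merge(one_hops)
  obs <- intersect_score(obs_merge$network, go)
  a_nodes <- anchor_nodes(anchors)
  base_layers <- fast_layer_edges(one_hops)
  go_key <- paste(go$node_a, go$node_b, sep = "\r")
  nulls <- vapply(seq_len(n_random), function(b) {
    rand <- lapply(seq_along(base_layers), function(i) {
      ed <- base_layers[[i]]
      nb <- ed$neighbors
      if (length(nb) == 0) return(ed)
      pool <- setdiff(universe, a_nodes)
      if (length(pool) < length(nb)) abort("universe too small to relabel")
      repl <- with_seed_opt(derive_seed(seed, sprintf("rand%d_%d", b, i)),
                            sample(pool, length(nb)))
      ia <- match(ed$a, nb); ib <- match(ed$b, nb)
      a2 <- ifelse(is.na(ia), ed$a, repl[ia])
      b2 <- ifelse(is.na(ib), ed$b, repl[ib])
      list(a = pmin(a2, b2), b = pmax(a2, b2), layer = ed$layer,
           neighbors = repl)
    })
    fast_score_intersect(rand, a_nodes, go_key, go$weight,
                         min_breadth, require_gwas)
  }, numeric(1))
  out <- null_validation(obs, nulls)
  out$observed_network <- obs_merge$network
  out$high_loe <- obs_merge$high_loe
  out
}

#' Hypergeometric GO term enrichment
#'
#' For each term overlapping the query set, computes the upper-tail
#' hypergeometric p-value of the overlap against the universe and applies
#' BH correction at level `q` across the tested terms. Terms with zero
#' overlap are skipped.
#'
#' @param genes Query gene set (must be contained in `universe`).
#' @param ann Annotation tibble `gene`, `term`.
#' @param universe All gene ids.
#' @param q BH level (default 0.1).
#' @return Tibble `term`, `overlap`, `term_size`, `query_size`,
#'   `universe_size`, `p_value`, `q_value`, `significant`.
#' @export
go_enrichment <- function(genes, ann, universe, q = 0.1) {
  genes <- unique(genes)
  if (!all(genes %in% universe)) abort("query genes must be a subset of the universe")
  empty <- tibble(term = character(), overlap = integer(),
                  term_size = integer(), query_size = integer(),
                  universe_size = integer(), p_value = double(),
                  q_value = double(), significant = logical())
  if (length(genes) == 0) return(empty)
  ann <- distinct(as_tibble(ann)[c("gene", "term")]) |>
    filter(.data$gene %in% universe)
  N <- length(unique(universe))
  sizes <- count(ann, .data$term, name = "term_size")
  hits <- ann |>
    filter(.data$gene %in% genes) |>
    count(.data$term, name = "overlap")
  if (nrow(hits) == 0) return(empty)
  res <- inner_join(hits, sizes, by = "term") |>
    mutate(query_size = length(genes), universe_size = N,
           p_value = stats::phyper(.data$overlap - 1, .data$term_size,
                                   N - .data$term_size, length(genes),
                                   lower.tail = FALSE))
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value <= q
  arrange(res, .data$p_value)
}
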