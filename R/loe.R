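# The LOE method proper: 1-hop anchor neighborhoods, breadth/depth scoring,
# threshold + merge, tier ranking, known-gene filtering.

#' Extract the 1-hop neighborhood of the anchor set
#'
#' Keeps every edge incident to at least one anchor node (gene or
#' metabolite), plus the endpoints of those edges; edges between two
#' non-anchor nodes are discarded. Anchors absent from the network are
#' reported once with a count.
#'
#' @param net An `loe_network` (single layer).
#' @param anchors An [anchor_set()].
#' @return An `loe_network` with subclass `one_hop` and attributes
#'   `anchors` (anchor nodes with at least one retained edge) and
#'   `neighbors` (non-anchor endpoints).
#' @export
extract_one_hop <- function(net, anchors) {
  a_nodes <- anchor_nodes(anchors)
  present <- unique(c(net$node_a, net$node_b))
  missing_anchors <- setdiff(a_nodes, present)
  if (length(missing_anchors) > 0) {
    inform(sprintf("%d anchor(s) absent from the network", length(missing_anchors)))
  }
  keep <- net$node_a %in% a_nodes | net$node_b %in% a_nodes
  oh <- loe_network(as_tibble(net)[keep, , drop = FALSE])
  nodes <- unique(c(oh$node_a, oh$node_b))
  attr(oh, "anchors") <- intersect(a_nodes, nodes)
  attr(oh, "neighbors") <- setdiff(nodes, a_nodes)
  class(oh) <- unique(c("one_hop", class(oh)))
  oh
}

# Long (gene, partner, layer, sign) table of anchor connections across a
# list of one-hop networks. Anchor-anchor edges contribute to both endpoints
# when include_anchors is TRUE, otherwise to neither.
anchor_connections <- function(one_hops, a_nodes, include_anchors = FALSE) {
  rows <- lapply(one_hops, function(oh) {
    if (nrow(oh) == 0) return(NULL)
    a_in <- oh$node_a %in% a_nodes
    b_in <- oh$node_b %in% a_nodes
    out <- list()
    sel <- b_in & (!a_in | include_anchors)
    out$x <- tibble(gene = oh$node_a[sel], partner = oh$node_b[sel],
                    layer = oh$layer[sel], sign = oh$sign[sel])
    sel <- a_in & (!b_in | include_anchors)
    out$y <- tibble(gene = oh$node_b[sel], partner = oh$node_a[sel],
                    layer = oh$layer[sel], sign = oh$sign[sel])
    bind_rows(out)
  })
  rows <- bind_rows(rows)
  if (nrow(rows) == 0) {
    rows <- tibble(gene = character(), partner = character(),
                   layer = character(), sign = character())
  }
  rows
}

#' Compute LOE breadth and depth scores
#'
#' For every non-anchor gene, the per-layer depth is the number of distinct
#' anchor nodes (genes or metabolites) it connects to in that layer's 1-hop
#' network; the breadth is the number of layers with non-zero depth; the
#' total depth sums depths over layers. The comethylation-discounted depth
#' (`depth_minus_cometh`) subtracts the comethylation depth from the total,
#' reflecting the lower-dimensional (hence less reliable) comethylation
#' signal. Coexpression anchor connections are additionally tallied by sign.
#'
#' @param one_hops List of 1-hop `loe_network`s, one per layer (layer names
#'   must be unique across the list).
#' @param anchors An [anchor_set()].
#' @param universe Optional character vector of all gene ids; genes absent
#'   from every layer then appear with zero scores.
#' @param include_anchors If `TRUE`, anchor genes are scored too (by their
#'   anchor partners); by default they are excluded from the candidate table.
#' @return A tibble of class `loe_scores`: `gene`, one `depth_<layer>`
#'   column per layer, `breadth`, `depth_total`, `depth_minus_cometh`,
#'   `n_pos_coexpr`, `n_neg_coexpr`. Attributes `layers` and `anchor_nodes`.
#' @export
compute_loe_scores <- function(one_hops, anchors, universe = NULL,
                               include_anchors = FALSE) {
  layers <- unlist(lapply(one_hops, function(x) unique(x$layer)))
  layers <- layers[!is.na(layers)]
  if (anyDuplicated(layers)) {
    abort(sprintf("duplicate layer name: %s", layers[duplicated(layers)][1]))
  }
  if (length(layers) == 0) layers <- character()
  a_nodes <- anchor_nodes(anchors)
  conn <- anchor_connections(one_hops, a_nodes, include_anchors)
  if (nrow(conn) > 0 && !include_anchors) {
    conn <- filter(conn, !(.data$gene %in% a_nodes))
  }
  conn <- filter(conn, node_kind(.data$gene) == "gene")
  depth <- conn |>
    distinct(.data$gene, .data$layer, .data$partner) |>
    count(.data$gene, .data$layer, name = "depth")
  genes <- union(unique(conn$gene), universe %||% character())
  if (include_anchors) {
    present <- unique(unlist(lapply(one_hops, function(x) c(x$node_a, x$node_b))))
    genes <- union(genes, intersect(a_nodes, present))
  } else {
    genes <- setdiff(genes, a_nodes)
  }
  genes <- sort(genes[node_kind(genes) == "gene"])
  wide <- tibble(gene = genes)
  for (ly in layers) {
    d <- filter(depth, .data$layer == ly)
    wide[[paste0("depth_", ly)]] <-
      replace_na(d$depth[match(genes, d$gene)], 0L)
  }
  depth_cols <- paste0("depth_", layers, recycle0 = TRUE)
  dm <- if (length(depth_cols)) as.matrix(wide[depth_cols]) else
    matrix(0L, nrow(wide), 0)
  wide$breadth <- as.integer(rowSums(dm > 0))
  wide$depth_total <- as.integer(rowSums(dm))
  cometh <- if ("depth_comethylation" %in% depth_cols)
    wide$depth_comethylation else 0L
  wide$depth_minus_cometh <- wide$depth_total - cometh
  cx <- conn |>
    filter(.data$layer == "coexpression") |>
    distinct(.data$gene, .data$partner, .data$sign)
  pos <- count(filter(cx, .data$sign == "+"), .data$gene)
  neg <- count(filter(cx, .data$sign == "-"), .data$gene)
  wide$n_pos_coexpr <- replace_na(pos$n[match(genes, pos$gene)], 0L)
  wide$n_neg_coexpr <- replace_na(neg$n[match(genes, neg$gene)], 0L)
  structure(wide, layers = layers, anchor_nodes = a_nodes,
            class = c("loe_scores", class(wide)))
}

#' Threshold scored genes and merge the layer networks
#'
#' A gene is "high-LOE" iff its breadth reaches `min_breadth` and (unless
#' `require_gwas = FALSE`) it carries at least one metabolite-GWAS
#' association (traditional or rare variant) -- a measurable phenotype link.
#' The merged network is the union of all 1-hop edges whose endpoints are
#' both anchors or high-LOE genes, each edge keeping its source layer.
#'
#' @param one_hops List of 1-hop `loe_network`s (same list scored).
#' @param scores The [compute_loe_scores()] output for those layers.
#' @param min_breadth Breadth threshold (default 3).
#' @param require_gwas Require >= 1 GWAS association (default `TRUE`).
#' @return List of class `loe_merge`: `network` (merged `loe_network`),
#'   `high_loe` (character vector of high-LOE genes).
#' @export
threshold_and_merge <- function(one_hops, scores, min_breadth = 3,
                                require_gwas = TRUE) {
  gw <- rep(0L, nrow(scores))
  for (col in c("depth_gwas_traditional", "depth_gwas_rare")) {
    if (col %in% names(scores)) gw <- gw + scores[[col]]
  }
  high <- scores$gene[scores$breadth >= min_breadth &
                        (!require_gwas | gw >= 1)]
  a_nodes <- attr(scores, "anchor_nodes")
  allowed <- c(a_nodes, high)
  kept <- lapply(one_hops, function(oh) {
    as_tibble(oh)[oh$node_a %in% allowed & oh$node_b %in% allowed, ]
  })
  merged <- merge_networks(lapply(kept, loe_network))
  structure(list(network = merged, high_loe = sort(high)),
            class = "loe_merge")
}

#' Assign priority tiers to high-LOE genes
#'
#' Tier 1: breadth >= 4, or breadth = 3 with comethylation-discounted depth
#' >= 5. Tier 2: breadth = 3 with discounted depth exactly 4. Tier 3: the
#' rest (discounted depth <= 3). Within tiers, genes are sorted by breadth
#' (descending), discounted depth (descending), then gene id, giving a
#' deterministic within-tier rank.
#'
#' @param scores An `loe_scores` table.
#' @param high_loe Character vector of high-LOE genes (all must be scored).
#' @return Tibble of class `tier_assignment`: `gene`, `breadth`,
#'   `depth_minus_cometh`, `tier`, `rank` (within tier).
#' @export
rank_tiers <- function(scores, high_loe) {
  missing <- setdiff(high_loe, scores$gene)
  if (length(missing) > 0) {
    abort(sprintf("gene(s) absent from scores: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  out <- as_tibble(scores)[match(high_loe, scores$gene),
                           c("gene", "breadth", "depth_minus_cometh")] |>
    mutate(tier = case_when(
      .data$breadth >= 4 ~ 1L,
      .data$breadth == 3 & .data$depth_minus_cometh >= 5 ~ 1L,
      .data$breadth == 3 & .data$depth_minus_cometh == 4 ~ 2L,
      TRUE ~ 3L)) |>
    arrange(.data$tier, desc(.data$breadth), desc(.data$depth_minus_cometh),
            .data$gene) |>
    group_by(.data$tier) |>
    mutate(rank = row_number()) |>
    ungroup()
  class(out) <- c("tier_assignment", class(out))
  out
}

#' Remove genes with previously documented roles
#'
#' Drops candidates found in an exclusion list (e.g. from a literature
#' review), preserving tiers and within-tier order, and reports the number
#' removed per tier.
#'
#' @param tiers A `tier_assignment` table.
#' @param exclusion Character vector of gene ids to remove.
#' @return The filtered `tier_assignment`.
#' @export
filter_known <- function(tiers, exclusion) {
  removed <- filter(tiers, .data$gene %in% exclusion)
  if (nrow(removed) > 0) {
    cnt <- count(removed, .data$tier)
    inform(paste0("removed known genes: ",
                  paste(sprintf("%d from tier %d", cnt$n, cnt$tier),
                        collapse = ", ")))
  }
  out <- filter(tiers, !(.data$gene %in% exclusion))
  class(out) <- unique(c("tier_assignment", class(out)))
  out
}
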