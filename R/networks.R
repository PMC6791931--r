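# Layer networks as canonical edge tibbles.
#
# A network is a tibble with columns node_a, node_b, layer, weight, sign and
# class "loe_network". Edges are undirected and stored once under canonical
# node ordering (node_a < node_b); self-edges are rejected. Metabolite nodes
# carry the "met:" namespace, so node kinds are derivable from the id itself.

LAYER_NAMES <- c("coexpression", "comethylation", "snp_correlation",
                 "gwas_traditional", "gwas_rare", "eqtn")

#' Construct a layer network from an edge table
#'
#' @param edges Data frame with columns `node_a`, `node_b`, `weight` and
#'   optionally `sign` (`"+"`, `"-"` or `"n/a"`). Additional columns are kept.
#' @param layer Layer name recorded on every edge. Conventional names are
#'   `r paste0('\x60', LAYER_NAMES, '\x60', collapse = ", ")`, but any
#'   string is accepted (a merged network mixes several).
#' @param check_layer If `TRUE`, require `layer` to be one of the conventional
#'   layer names.
#' @return A tibble of class `loe_network` with columns
#'   `node_a`, `node_b`, `layer`, `weight`, `sign`, one row per edge,
#'   canonically ordered (so the result is independent of edge insertion
#'   order).
#' @details Self-edges raise an error. Duplicate canonical edges within one
#'   layer raise an error; layer builders are responsible for collapsing
#'   multiplicities before construction.
#' @export
#' @examples
#' loe_network(data.frame(node_a = "g2", node_b = "g1", weight = 0.9),
#'             layer = "coexpression")
loe_network <- function(edges, layer = NULL, check_layer = FALSE) {
  edges <- as_tibble(edges)
  if (nrow(edges) == 0) {
    out <- tibble(node_a = character(), node_b = character(),
                  layer = character(), weight = double(), sign = character())
    class(out) <- c("loe_network", class(out))
    return(out)
  }
  if (!is.null(layer)) edges$layer <- layer
  if (!"layer" %in% names(edges)) {
    abort("edges need a `layer` column or a `layer` argument")
  }
  if (check_layer && !all(edges$layer %in% LAYER_NAMES)) {
    abort(sprintf("unknown layer name(s): %s",
                  paste(setdiff(unique(edges$layer), LAYER_NAMES), collapse = ", ")))
  }
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (!"sign" %in% names(edges)) {
    edges$sign <- ifelse(edges$weight < 0, "-", "+")
  }
  if (any(edges$node_a == edges$node_b)) {
    bad <- edges$node_a[edges$node_a == edges$node_b][1]
    abort(sprintf("self-edge on node '%s' is not allowed", bad))
  }
  swap <- edges$node_a > edges$node_b
  tmp <- edges$node_a[swap]
  edges$node_a[swap] <- edges$node_b[swap]
  edges$node_b[swap] <- tmp
  edges <- edges |>
    select("node_a", "node_b", "layer", "weight", "sign", dplyr::everything()) |>
    arrange(.data$layer, .data$node_a, .data$node_b)
  key <- paste(edges$layer, edges$node_a, edges$node_b)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate edge within a layer: %s", key[duplicated(key)][1]))
  }
  attr(edges, "anchors") <- NULL
  attr(edges, "neighbors") <- NULL
  class(edges) <- c("loe_network", setdiff(class(edges), c("one_hop", "loe_network")))
  edges
}

#' All node ids of a network
#' @param net An `loe_network`.
#' @return Sorted character vector of node ids.
#' @export
network_nodes <- function(net) {
  sort(unique(c(net$node_a, net$node_b)))
}

#' Merge several networks into one multi-layer network
#'
#' Edge union with per-edge layer provenance preserved: an edge contributed by
#' two layers appears as two rows with the same canonical node pair and
#' different `layer` labels. The union is commutative and associative.
#'
#' @param nets List of `loe_network` objects (or a single network; empty
#'   networks are allowed).
#' @return An `loe_network` containing the distinct `(node_a, node_b, layer)`
#'   rows of all inputs.
#' @details Node kinds are carried by the `met:` namespace, so a node id can
#'   never be typed both gene and metabolite; the invariant is asserted anyway.
#' @export
merge_networks <- function(nets) {
  if (inherits(nets, "loe_network")) nets <- list(nets)
  nets <- nets[vapply(nets, nrow, 1L) > 0]
  if (length(nets) == 0) return(loe_network(tibble()))
  all_edges <- bind_rows(lapply(nets, function(x) as_tibble(x)[
    c("node_a", "node_b", "layer", "weight", "sign")]))
  all_edges <- distinct(all_edges, .data$node_a, .data$node_b, .data$layer,
                        .keep_all = TRUE)
  nodes <- c(all_edges$node_a, all_edges$node_b)
  stopifnot(all(node_kind(nodes) %in% c("gene", "metabolite")))
  loe_network(all_edges)
}

#' @export
print.loe_network <- function(x, ...) {
  cat(sprintf("# LOE network: %d edge(s), %d node(s), layer(s): %s\n",
              nrow(x), length(network_nodes(x)),
              paste(unique(x$layer), collapse = ", ")))
  NextMethod()
}
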