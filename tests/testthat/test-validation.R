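# Randomization validations: within-row shuffles, correlation subsampling,
# rank-sum comparison, GO network, label randomization, intersect score,
# hypergeometric enrichment.

rand_matrix <- function(nr, nc, seed = 1) {
  withr::with_seed(seed, matrix(runif(nr * nc), nr, nc,
                                dimnames = list(sprintf("g%03d", 1:nr),
                                                sprintf("s%02d", 1:nc))))
}

test_that("within-row shuffling preserves row multisets and respects seeds", {
  m1 <- rand_matrix(5, 1)
  expect_identical(shuffle_within_rows(m1, seed = 4), m1)
  m <- rand_matrix(10, 10, seed = 2)
  s1 <- shuffle_within_rows(m, seed = 9)
  for (i in 1:10) expect_equal(unname(sort(s1[i, ])), unname(sort(m[i, ])))
  expect_identical(shuffle_within_rows(m, seed = 9), s1)
  expect_false(identical(shuffle_within_rows(m, seed = 10), s1))
})

test_that("correlation subsampling covers the exact pair multiset", {
  m <- rand_matrix(2, 8, seed = 3)
  expect_equal(subsample_correlations(m, 1, seed = 1),
               cor(m[1, ], m[2, ], method = "spearman"))
  m5 <- rand_matrix(5, 12, seed = 4)
  full <- subsample_correlations(m5, 10, seed = 1)
  rho <- cor(t(m5), method = "spearman")
  expect_equal(sort(full), sort(rho[upper.tri(rho)]), tolerance = 1e-12)
  expect_identical(subsample_correlations(m5, 4, seed = 7),
                   subsample_correlations(m5, 4, seed = 7))
  expect_error(subsample_correlations(m5, 11, seed = 1), "replace")
  expect_error(subsample_correlations(m5[1, , drop = FALSE], 1), "2 non-constant")
})

test_that("rank-sum comparison is exact on small samples and detects shifts", {
  rs <- ranksum_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p_value, 0.1)
  same <- ranksum_compare(1:20, 1:20)
  expect_gt(same$p_value, 0.9)
  withr::with_seed(6, {
    x <- rnorm(1000) + 10; y <- rnorm(1000)
    expect_lt(ranksum_compare(x, y)$p_value, 1e-10)
  })
})

test_that("GO network weights, size cap and max-edge collapse are correct", {
  ann <- tibble::tibble(gene = c("A", "B", "A", "B", "C"),
                        term = c("T1", "T1", "T2", "T2", "T2"))
  go <- build_go_network(ann)
  expect_equal(nrow(go), 3L)
  w <- setNames(go$weight, paste(go$node_a, go$node_b))
  expect_equal(w[["A B"]], 1 / 2)
  expect_equal(w[["A C"]], 1 / 3)
  expect_equal(w[["B C"]], 1 / 3)
  expect_identical(go$term[go$node_a == "A" & go$node_b == "B"], "T1")
  # a term past the size cap contributes nothing
  big <- tibble::tibble(gene = sprintf("x%04d", 1:1001), term = "TBIG")
  expect_equal(nrow(build_go_network(big, max_term_size = 1000)), 0L)
  # single-gene terms produce no edges
  expect_equal(nrow(build_go_network(tibble::tibble(gene = "A", term = "T9"),
                                     max_term_size = 10)), 0L)
})

one_hop_fixture <- function() {
  anchors <- anchor_set(c("A1", "A2"))
  net <- loe_network(tibble::tibble(
    node_a = c("A1", "A1", "A2", "A1"),
    node_b = c("n1", "n2", "n2", "A2"),
    weight = 1), layer = "coexpression")
  suppressMessages(extract_one_hop(net, anchors))
}

test_that("neighbor randomization preserves structure exactly", {
  oh <- one_hop_fixture()
  universe <- sprintf("u%02d", 1:10)
  deg <- function(net) {
    nodes <- c(net$node_a, net$node_b)
    table(nodes[nodes %in% c("A1", "A2")])
  }
  for (s in 1:50) {
    r <- randomize_one_hop(oh, universe, seed = s)
    expect_equal(nrow(r), nrow(oh))
    expect_equal(length(network_nodes(r)), length(network_nodes(oh)))
    expect_identical(deg(r), deg(oh))
    expect_true(all(setdiff(network_nodes(r), c("A1", "A2")) %in% universe))
  }
  # no neighbors: nothing to relabel
  aa <- loe_network(tibble::tibble(node_a = "A1", node_b = "A2", weight = 1),
                    layer = "coexpression")
  oh_aa <- suppressMessages(extract_one_hop(aa, anchor_set(c("A1", "A2"))))
  expect_identical(as.data.frame(randomize_one_hop(oh_aa, universe, 1)),
                   as.data.frame(oh_aa))
  expect_error(randomize_one_hop(oh, c("u1", "A1"), seed = 1), "too small")
})

test_that("replacement labels are drawn uniformly from the universe", {
  oh <- one_hop_fixture()   # 2 distinct neighbors
  universe <- sprintf("u%02d", 1:10)
  counts <- setNames(numeric(10), universe)
  n_rand <- 1000
  for (s in seq_len(n_rand)) {
    r <- randomize_one_hop(oh, universe, seed = 10000 + s)
    picked <- setdiff(network_nodes(r), c("A1", "A2"))
    counts[picked] <- counts[picked] + 1
  }
  p <- 2 / 10   # each label picked with prob k/|pool|
  sigma <- sqrt(n_rand * p * (1 - p))
  expect_true(all(abs(counts - n_rand * p) <= 3.5 * sigma))
})

test_that("intersect score sums shared-pair GO weights once", {
  go <- structure(tibble::tibble(node_a = c("A", "B"), node_b = c("B", "C"),
                                 weight = c(0.5, 1 / 3), term = c("T1", "T2")),
                  class = c("go_network", class(tibble::tibble())))
  net <- loe_network(tibble::tibble(node_a = c("A", "A", "A"),
                                    node_b = c("B", "D", "met:m1"),
                                    weight = 1), layer = "coexpression")
  expect_equal(intersect_score(net, go), 0.5)
  disjoint <- loe_network(tibble::tibble(node_a = "X", node_b = "Y", weight = 1),
                          layer = "coexpression")
  expect_equal(intersect_score(disjoint, go), 0)
  # a network intersected with itself as a 0/1-weighted GO network counts edges
  self_go <- structure(tibble::tibble(node_a = c("A", "A"), node_b = c("B", "D"),
                                      weight = 1, term = "T"),
                       class = c("go_network", class(tibble::tibble())))
  expect_equal(intersect_score(net, self_go), 2)
  # multi-layer duplicates of a pair still count once
  dup <- merge_networks(list(net, loe_network(tibble::tibble(
    node_a = "A", node_b = "B", weight = 1), layer = "comethylation")))
  expect_equal(intersect_score(dup, go), 0.5)
  expect_lte(intersect_score(dup, go), sum(go$weight))
})

test_that("null summaries use the add-one empirical p-value", {
  nv <- null_validation(10, runif(100, 0, 5))
  expect_equal(nv$p_value, 1 / 101)
  expect_equal(null_validation(3, rep(3, 7))$p_value, 1)
  expect_equal(null_validation(-2, rep(3, 7))$p_value, 1)
  expect_equal(nv$n, 100L)
})

test_that("hypergeometric enrichment matches closed forms and the sum oracle", {
  universe <- sprintf("u%02d", 1:10)
  ann <- tibble::tibble(gene = universe[1:4], term = "T1")
  res <- go_enrichment(universe[1:3], ann, universe)
  expect_equal(res$p_value, 1 / 30)
  # query = universe: overlap is forced, p = 1
  res_all <- go_enrichment(universe, ann, universe)
  expect_equal(res_all$p_value, 1)
  # disjoint term skipped
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(gene = universe[5:6], term = "T2"))
  res2 <- go_enrichment(universe[1:3], ann2, universe)
  expect_false("T2" %in% res2$term)
  expect_error(go_enrichment("nope", ann, universe), "subset")
  withr::with_seed(77, {
    for (rep in 1:20) {
      N <- sample(6:15, 1)
      uni <- sprintf("v%02d", 1:N)
      terms <- tibble::tibble(
        gene = sample(uni, 3 * N, replace = TRUE),
        term = sample(paste0("T", 1:4), 3 * N, replace = TRUE)) |>
        dplyr::distinct()
      query <- sample(uni, sample(2:N, 1))
      res <- go_enrichment(query, terms, uni)
      for (i in seq_len(nrow(res))) {
        expect_equal(res$p_value[i],
                     oracle_hyper_upper(res$overlap[i], res$term_size[i],
                                        N, length(query)),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("shuffle validation separates planted blocks from shuffled data", {
  genes <- sprintf("g%03d", 1:60)
  blocks <- split(genes[1:50], rep(1:5, each = 10))
  m <- simulate_block_matrix(genes, 48, blocks, target_rho = 0.9,
                             global_rho = 0.2, seed = 21)
  sv <- validate_shuffle(m, threshold = 0.85, n_shuffles = 5,
                         n_subsample = 1500, seed = 5)
  expect_lt(sv$p_value, 0.01)
  expect_gt(sv$frac_observed, 10 * sv$frac_shuffled)
  g <- glance(sv)
  expect_equal(g$p_value, sv$p_value)
  expect_s3_class(autoplot(sv), "ggplot")
})

test_that("the GO-validation randomization loop matches the regular pipeline", {
  fx <- random_multilayer(n_genes = 50, n_layers = 5, mean_edges = 30,
                          seed = 404)
  withr::with_seed(405, {
    ann <- tibble::tibble(
      gene = sample(sprintf("G%04d", 1:50), 120, replace = TRUE),
      term = sample(paste0("T", 1:12), 120, replace = TRUE)) |>
      dplyr::distinct()
  })
  go <- build_go_network(ann, max_term_size = 20)
  universe <- sprintf("G%04d", 1:50)
  v <- validate_go_network(fx$one_hops, fx$anchors, go, universe,
                           n_random = 8, min_breadth = 2, seed = 6)
  slow <- vapply(1:8, function(b) {
    rand <- lapply(seq_along(fx$one_hops), function(i) {
      randomize_one_hop(fx$one_hops[[i]], universe,
                        seed = loescore:::derive_seed(6, sprintf("rand%d_%d", b, i)),
                        anchors = fx$anchors)
    })
    sc <- compute_loe_scores(rand, fx$anchors)
    mg <- threshold_and_merge(rand, sc, min_breadth = 2)
    intersect_score(mg$network, go)
  }, numeric(1))
  expect_equal(v$null, slow)
  obs <- intersect_score(
    threshold_and_merge(fx$one_hops,
                        compute_loe_scores(fx$one_hops, fx$anchors),
                        min_breadth = 2)$network, go)
  expect_equal(v$observed, obs)
})
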