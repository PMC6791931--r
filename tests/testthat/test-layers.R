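# Layer builders: Spearman correlation layers, the CCC co-segregation
# measure, SNP-to-gene projection and association layers.

make_matrix <- function(vals, ids = NULL) {
  m <- do.call(rbind, vals)
  rownames(m) <- ids %||% paste0("g", seq_along(vals))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("perfect monotone pairs produce unit-weight signed edges", {
  m <- make_matrix(list(c(1, 2, 3, 4), c(10, 20, 30, 40), c(4, 3, 2, 1)))
  net <- build_correlation_layer(m, threshold = 0.99)
  expect_equal(nrow(net), 3L)  # all three pairs are |rho| = 1
  up <- net[net$node_a == "g1" & net$node_b == "g2", ]
  expect_equal(up$weight, 1)
  expect_equal(up$sign, "+")
  dn <- net[net$node_a == "g1" & net$node_b == "g3", ]
  expect_equal(dn$weight, -1)
  expect_equal(dn$sign, "-")
})

test_that("correlation layer matches the brute-force all-pairs oracle", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      n_g <- sample(c(5, 20, 50), 1)
      n_s <- sample(c(10, 20), 1)
      m <- matrix(rnorm(n_g * n_s), n_g, n_s,
                  dimnames = list(sprintf("g%02d", 1:n_g), paste0("s", 1:n_s)))
      # inject correlated pairs and ties so thresholds actually bite
      m[2, ] <- m[1, ] + rnorm(n_s, sd = 0.05)
      m[3, ] <- round(m[1, ], 1)
      thr <- runif(1, 0.3, 0.9)
      net <- build_correlation_layer(m, thr)
      orc <- oracle_correlation_edges(m, thr)
      expect_equal(nrow(net), nrow(orc))
      expect_equal(net$node_a, orc$node_a)
      expect_equal(net$node_b, orc$node_b)
      expect_equal(net$weight, orc$rho, tolerance = 1e-12)
    }
  })
})

test_that("zero-variance features are excluded with a message", {
  m <- make_matrix(list(c(1, 1, 1, 1), c(1, 2, 3, 4), c(2, 4, 6, 8)))
  expect_message(net <- build_correlation_layer(m, 0.5), "zero-variance")
  expect_false("g1" %in% c(net$node_a, net$node_b))
  expect_equal(nrow(net), 1L)
})

test_that("edge count is monotone non-increasing in the threshold", {
  withr::with_seed(13, {
    m <- matrix(rnorm(30 * 12), 30, 12,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:12)))
    counts <- vapply(seq(0.1, 1, by = 0.1),
                     function(t) nrow(build_correlation_layer(m, t)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("CCC normalization, symmetry and missing handling behave", {
  # balanced homozygous co-segregation attains the maximum of 1
  a <- c(0L, 0L, 2L, 2L, 0L, 2L)
  expect_equal(ccc(a, a), 1)
  expect_equal(ccc(a, 2L - a), 1)  # complementary pattern co-segregates too
  withr::with_seed(99, {
    for (rep in 1:200) {
      x <- sample(0:2, 8, replace = TRUE)
      y <- sample(0:2, 8, replace = TRUE)
      v1 <- ccc(x, y); v2 <- ccc(y, x)
      expect_equal(v1, v2, tolerance = 1e-14)
      expect_gte(v1, 0); expect_lte(v1, 1)
    }
  })
  expect_warning(v <- ccc(c(0L, NA, NA), c(NA, 1L, 2L)), "informative")
  expect_true(is.na(v))
  # pairwise-complete: missing samples are dropped, not imputed
  expect_equal(ccc(c(0L, 0L, 2L, 2L, NA), c(0L, 0L, 2L, 2L, 1L)), 1)
})

test_that("CCC equals its brute-force reference transcription to 1e-12", {
  withr::with_seed(7, {
    for (rep in 1:100) {
      n <- sample(4:10, 1)
      x <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.2, 0.4))
      y <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.2, 0.4))
      if (runif(1) < 0.3) x[sample(n, 1)] <- NA
      v <- suppressWarnings(ccc(x, y))
      o <- oracle_ccc(x, y)
      if (is.na(o)) expect_true(is.na(v)) else expect_equal(v, o, tolerance = 1e-12)
    }
  })
  # exhaustive enumeration of all 3^3 x 3^3 length-3 dosage pairs
  grid <- expand.grid(a1 = 0:2, a2 = 0:2, a3 = 0:2)
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      x <- as.integer(grid[i, ]); y <- as.integer(grid[j, ])
      expect_equal(ccc(x, y), oracle_ccc(x, y), tolerance = 1e-12)
    }
  }
})

test_that("ccc_matrix agrees with the scalar CCC, with and without missing data", {
  withr::with_seed(17, {
    dos <- matrix(sample(0:2, 8 * 12, replace = TRUE), 8, 12,
                  dimnames = list(paste0("s", 1:8), paste0("i", 1:12)))
    cm <- ccc_matrix(dos)
    for (i in 1:7) for (j in (i + 1):8) {
      expect_equal(cm[i, j], ccc(dos[i, ], dos[j, ]), tolerance = 1e-12)
    }
    dos[sample(length(dos), 10)] <- NA
    cm2 <- ccc_matrix(dos)
    expect_equal(cm2[1, 2], suppressWarnings(ccc(dos[1, ], dos[2, ])),
                 tolerance = 1e-12)
  })
})

snp_fixture <- function(dos_list, chrom, pos, genes) {
  dos <- do.call(rbind, dos_list)
  rownames(dos) <- paste0("snp", seq_along(dos_list))
  colnames(dos) <- paste0("s", seq_len(ncol(dos)))
  g <- genotype_matrix(dos, tibble::tibble(snp_id = rownames(dos),
                                           chrom = chrom, pos = as.integer(pos)))
  list(g = g, genes = genes)
}

test_that("SNP layer applies the distance rule and projects to genes", {
  pat <- c(0L, 2L, 0L, 2L, 2L, 0L)
  genes <- tibble::tibble(gene_id = c("gA", "gB", "gC"),
                          chrom = c("c1", "c1", "c2"),
                          start = c(1000L, 6000L, 1000L),
                          end = c(2000L, 7000L, 2000L), strand = "+")
  # 5 kb apart on one chromosome: no edge despite CCC = 1
  fx <- snp_fixture(list(pat, pat), c("c1", "c1"), c(1500, 6500), genes)
  expect_equal(nrow(build_snp_correlation_layer(fx$g, genes)), 0L)
  # different chromosomes, distinct genes: one edge of weight 1
  fx <- snp_fixture(list(pat, pat), c("c1", "c2"), c(1500, 1500), genes)
  net <- build_snp_correlation_layer(fx$g, genes)
  expect_equal(nrow(net), 1L)
  expect_identical(c(net$node_a, net$node_b), c("gA", "gC"))
  expect_equal(net$weight, 1)
  expect_identical(net$layer, "snp_correlation")
})

test_that("SNP pairs hitting one gene pair collapse to the maximum CCC", {
  # three qualifying SNP pairs between gA and gC with controlled CCC values
  flip_k <- function(pat, k) { out <- pat; out[seq_len(k)] <- 2L - out[seq_len(k)]; out }
  pat <- rep(c(0L, 2L), 10)
  genes <- tibble::tibble(gene_id = c("gA", "gC"), chrom = c("c1", "c2"),
                          start = c(1000L, 1000L), end = c(3000L, 3000L),
                          strand = "+")
  fx <- snp_fixture(
    list(pat, flip_k(pat, 3), pat, flip_k(pat, 2), pat, flip_k(pat, 1)),
    rep(c("c1", "c2"), 3), c(1100, 1100, 1200, 1200, 1300, 1300), genes)
  cm <- ccc_matrix(fx$g$dosages)
  vals <- c(cm[1, 2], cm[3, 4], cm[5, 6])
  expect_true(all(vals >= 0.7), info = "fixture pairs must qualify")
  net <- build_snp_correlation_layer(fx$g, genes)
  expect_equal(nrow(net), 1L)
  # only cross-chromosome pairs qualify (same-chromosome ones are < 10 kb)
  chrom <- fx$g$meta$chrom
  cross <- outer(chrom, chrom, "!=") & upper.tri(cm)
  expect_equal(net$weight, max(cm[cross]))
})

test_that("SNP layer is invariant to SNP and sample order", {
  withr::with_seed(41, {
    dos <- matrix(sample(0:2, 10 * 20, replace = TRUE, prob = c(.4, .2, .4)),
                  10, 20, dimnames = list(paste0("snp", 1:10), paste0("s", 1:20)))
    dos[2, ] <- dos[1, ]  # one perfect pair
    genes <- tibble::tibble(gene_id = paste0("g", 1:10),
                            chrom = rep(c("c1", "c2"), 5),
                            start = rep(seq(1000, 100000, length.out = 5), each = 2),
                            end = rep(seq(1000, 100000, length.out = 5), each = 2) + 500,
                            strand = "+")
    genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)
    pos <- genes$start + 100L
    g1 <- genotype_matrix(dos, tibble::tibble(snp_id = rownames(dos),
                                              chrom = genes$chrom, pos = pos))
    perm_snp <- sample(10); perm_samp <- sample(20)
    g2 <- genotype_matrix(dos[perm_snp, perm_samp],
                          tibble::tibble(snp_id = rownames(dos)[perm_snp],
                                         chrom = genes$chrom[perm_snp],
                                         pos = pos[perm_snp]))
    n1 <- build_snp_correlation_layer(g1, genes, ccc_min = 0.5)
    n2 <- build_snp_correlation_layer(g2, genes, ccc_min = 0.5)
    expect_equal(as.data.frame(n1), as.data.frame(n2))
  })
})

test_that("association layers map SNPs through flanked gene intervals", {
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = c("c1", "c1"),
                          start = c(2000L, 2500L), end = c(3000L, 4000L),
                          strand = "+")
  snp_meta <- tibble::tibble(snp_id = c("s1", "s2"), chrom = "c1",
                             pos = c(1500L, 9000L))
  assoc <- tibble::tibble(
    unit_id = c("gA", "s1", "s2", "gB"),
    phenotype_id = c("m1", "m2", "m2", "m3"),
    p_value = c(1e-4, 1e-5, 1e-6, 0.9),
    q_value = c(0.01, 0.01, 0.01, 0.8),
    layer_tag = c("gwas_rare", "gwas_rare", "gwas_rare", "gwas_rare"))
  net <- build_association_layer(assoc, genes, snp_meta, flank_bp = 2000,
                                 layer_tag = "gwas_rare")
  # gene-level row passes through; s1 maps into gA [0, 5000] and gB [500, 6000];
  # s2 maps nowhere; gB direct row fails the q cutoff
  expect_setequal(paste(net$node_a, net$node_b),
                  c("gA met:m1", "gA met:m2", "gB met:m2"))
  expect_equal(net$weight[net$node_a == "gA" & net$node_b == "met:m2"], 5)
  # strict gene bodies: s1 at 1500 maps to no gene with flank 0
  net0 <- suppressMessages(
    build_association_layer(assoc, genes, snp_meta, flank_bp = 0,
                            layer_tag = "gwas_rare"))
  expect_setequal(paste(net0$node_a, net0$node_b), "gA met:m1")
})

test_that("association layer applies BH when q-values are absent", {
  genes <- tibble::tibble(gene_id = "gA", chrom = "c1", start = 1L,
                          end = 100L, strand = "+")
  assoc <- tibble::tibble(unit_id = "gA",
                          phenotype_id = c("m1", "m2", "m3", "m4"),
                          p_value = c(0.01, 0.02, 0.03, 0.5),
                          q_value = NA_real_, layer_tag = "gwas_traditional")
  net <- build_association_layer(assoc, genes, layer_tag = "gwas_traditional",
                                 q_max = 0.1)
  expect_equal(nrow(net), 3L)
})
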