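# Desk-scale synthetic multi-omic worlds with planted anchor connectivity,
# co-segregating SNP pairs, association edges and GO structure, plus the
# ground-truth manifest every planted signal implies. Planted margins are
# wide and verified (with redraw of offending background features), so
# recovery assertions on emitted worlds are deterministic, not flaky.

#' Simulation configuration
#'
#' Defaults describe the package's reference study conditions: ~1,000 genes,
#' 20 anchor genes, 8 anchor metabolites, 64 expression samples and 10
#' methylation samples per gene (the dimensionality asymmetry that motivates
#' the comethylation discount in ranking), 100 genotyped samples, and 15
#' planted candidate genes spanning all tiers plus three designed failures
#' (insufficient breadth or no GWAS edge).
#'
#' @param n_genes Number of genes (default 1000).
#' @param n_anchor_genes Number of anchor genes (default 20).
#' @param n_metabolites Total metabolites (default 20).
#' @param n_anchor_metabolites Anchor metabolites among them (default 8).
#' @param n_samples_expr Expression samples (default 64).
#' @param n_samples_meth Methylation samples (default 10).
#' @param n_samples_geno Genotyped samples (default 100).
#' @param n_background_snps Background SNPs beyond the planted ones
#'   (default 60).
#' @param target_rho Latent within-block correlation for planted
#'   coexpression blocks (default 0.97; well above the 0.85 threshold so
#'   recovery is deterministic at 64 samples).
#' @param coexpr_threshold,cometh_threshold,ccc_min,min_dist_bp,fdr_q
#'   Layer thresholds the world is built against (defaults 0.85, 0.95, 0.7,
#'   10000, 0.1).
#' @param ld_flip_prob Per-sample flip probability when copying a planted
#'   co-segregating dosage pattern (default 0.02).
#' @param assoc_p_planted P-value given to planted association rows
#'   (default 1e-8).
#' @param n_background_assoc Background association rows per GWAS layer
#'   (default 200).
#' @param go_term_size_range Size range for planted (small, high-weight) GO
#'   terms (default 3..6).
#' @param n_background_terms,background_term_size Background GO terms over
#'   non-candidate genes (default 8 terms of 60 genes).
#' @param planted Planted-candidate design: a data frame with one row per
#'   candidate and integer columns `cx`, `cm`, `sc`, `gt`, `gr` giving the
#'   number of anchor partners per layer (coexpression, comethylation, SNP
#'   correlation, traditional GWAS, rare-variant GWAS). Defaults to
#'   [planted_design_default()].
#' @return A list of class `loe_sim_config`.
#' @export
loe_sim_config <- function(n_genes = 1000, n_anchor_genes = 20,
                           n_metabolites = 20, n_anchor_metabolites = 8,
                           n_samples_expr = 64, n_samples_meth = 10,
                           n_samples_geno = 100, n_background_snps = 60,
                           target_rho = 0.97,
                           coexpr_threshold = 0.85, cometh_threshold = 0.95,
                           ccc_min = 0.7, min_dist_bp = 10000, fdr_q = 0.1,
                           ld_flip_prob = 0.02, assoc_p_planted = 1e-8,
                           n_background_assoc = 200,
                           go_term_size_range = c(3, 6),
                           n_background_terms = 8, background_term_size = 60,
                           planted = planted_design_default()) {
  planted <- as_tibble(planted)
  stopifnot(all(c("cx", "cm", "sc", "gt", "gr") %in% names(planted)),
            target_rho > 0, target_rho < 1,
            n_anchor_genes >= max(sum(planted$cx), sum(planted$cm), sum(planted$sc)),
            n_anchor_metabolites >= max(planted$gt, planted$gr, 0),
            n_genes > n_anchor_genes + nrow(planted),
            n_metabolites >= n_anchor_metabolites)
  structure(as.list(environment()), class = "loe_sim_config")
}

#' Default planted-candidate design
#'
#' Fifteen candidates: five expected in tier 1, three in tier 2, four in
#' tier 3, and three designed to fail the merge threshold (breadth two, or
#' breadth three without any GWAS association).
#'
#' @return Tibble with columns `cx`, `cm`, `sc`, `gt`, `gr`.
#' @export
planted_design_default <- function() {
  tibble(
    cx = c(2L, 3L, 3L, 2L, 0L, 2L, 1L, 0L, 1L, 0L, 1L, 2L, 1L, 0L, 2L),
    cm = c(2L, 1L, 3L, 1L, 2L, 2L, 0L, 2L, 1L, 1L, 2L, 0L, 2L, 0L, 1L),
    sc = c(1L, 1L, 0L, 1L, 2L, 0L, 2L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 1L),
    gt = c(1L, 1L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 2L, 0L, 1L, 0L),
    gr = c(1L, 0L, 0L, 1L, 1L, 2L, 0L, 2L, 0L, 1L, 0L, 0L, 0L, 0L, 0L))
}

#' Simulate a feature matrix with planted correlation blocks
#'
#' Latent-Gaussian block model: genes in a planted block share a latent
#' factor (loading `sqrt(target_rho)`), background genes are independent
#' noise, and a monotone lognormal transform maps values to non-negative
#' TPM-like magnitudes while preserving every row's rank structure. When
#' `exact_ranks = TRUE`, block members are exact monotone copies of the
#' latent (pairwise Spearman exactly 1), the configuration used for the
#' low-dimensional methylation matrices. When `clean_threshold` is set, the
#' realized Spearman matrix is verified and background features taking part
#' in a spurious supra-threshold pair are redrawn, guaranteeing that the
#' only edges at the layer threshold are the planted ones.
#'
#' @param gene_ids Character vector of feature ids.
#' @param n_samples Number of samples.
#' @param blocks List of character vectors (disjoint subsets of `gene_ids`).
#' @param target_rho Latent pairwise correlation of block members.
#' @param global_rho Pairwise correlation induced by a single matrix-wide
#'   latent shared by every gene (default 0), emulating the tissue-driven
#'   global covariance of real expression atlases; must stay below
#'   `target_rho`.
#' @param exact_ranks Make block members exact rank copies of the latent.
#' @param clean_threshold Layer threshold to verify against (or `NULL`).
#' @param seed Integer seed.
#' @param max_iter Maximum verification/redraw rounds.
#' @return Feature x sample matrix of TPM-like values.
#' @export
simulate_block_matrix <- function(gene_ids, n_samples, blocks = list(),
                                  target_rho = 0.97, global_rho = 0,
                                  exact_ranks = FALSE,
                                  clean_threshold = NULL, seed = 1,
                                  max_iter = 30) {
  stopifnot(!anyDuplicated(unlist(blocks)), global_rho >= 0,
            global_rho < target_rho)
  if (length(blocks) > 0 && !all(unlist(blocks) %in% gene_ids)) {
    abort("block members must be drawn from gene_ids")
  }
  n_g <- length(gene_ids)
  block_of <- setNames(rep(NA_integer_, n_g), gene_ids)
  for (b in seq_along(blocks)) block_of[blocks[[b]]] <- b
  withr::with_seed(as.integer(seed), {
    common <- stats::rnorm(n_samples)
    base_row <- function() {
      sqrt(global_rho) * common +
        sqrt(1 - global_rho) * stats::rnorm(n_samples)
    }
    z <- matrix(0, n_g, n_samples, dimnames = list(gene_ids, NULL))
    for (i in seq_len(n_g)) z[i, ] <- base_row()
    draw_block <- function(b) {
      latent <- stats::rnorm(n_samples)
      for (g in blocks[[b]]) {
        z[g, ] <<- if (exact_ranks) {
          stats::runif(1, 0.5, 2) * latent + stats::rnorm(1)
        } else {
          sqrt(global_rho) * common +
            sqrt(target_rho - global_rho) * latent +
            sqrt(1 - target_rho) * stats::rnorm(n_samples)
        }
      }
    }
    for (b in seq_along(blocks)) draw_block(b)
    if (!is.null(clean_threshold)) {
      same_block <- outer(block_of, block_of,
                          function(a, b) !is.na(a) & !is.na(b) & a == b)
      for (iter in seq_len(max_iter)) {
        rho <- stats::cor(t(z), method = "spearman")
        bad_bg <- which(upper.tri(rho) & abs(rho) >= clean_threshold &
                          !same_block, arr.ind = TRUE)
        bad_pl <- which(upper.tri(rho) & abs(rho) < clean_threshold &
                          same_block, arr.ind = TRUE)
        if (nrow(bad_bg) == 0 && nrow(bad_pl) == 0) break
        redraw_blocks <- integer()
        for (r in seq_len(nrow(bad_bg))) {
          i <- bad_bg[r, 1]; j <- bad_bg[r, 2]
          if (is.na(block_of[i])) {
            z[i, ] <- base_row()
          } else if (is.na(block_of[j])) {
            z[j, ] <- base_row()
          } else {
            redraw_blocks <- c(redraw_blocks, max(block_of[i], block_of[j]))
          }
        }
        if (nrow(bad_pl) > 0) {
          redraw_blocks <- c(redraw_blocks, block_of[bad_pl[, 1]])
        }
        for (b in unique(redraw_blocks)) draw_block(b)
        if (iter == max_iter) abort("block matrix failed to stabilize; widen margins")
      }
    }
    out <- exp(1.2 * z + 6)
    colnames(out) <- sprintf("s%03d", seq_len(n_samples))
    out
  })
}

# Assign anchor partners per layer to the planted candidates. Within the
# expression, methylation and genotype matrices anchor budgets must be
# disjoint across candidates; anchor metabolites are reused round-robin.
assign_partners <- function(cfg, ids) {
  take_seq <- function(pool, counts) {
    off <- 0L
    lapply(counts, function(k) {
      out <- pool[seq_len(k) + off]
      off <<- off + k
      out
    })
  }
  take_cycle <- function(pool, counts) {
    off <- 0L
    lapply(counts, function(k) {
      if (k == 0) return(character())
      out <- pool[((off + seq_len(k) - 1L) %% length(pool)) + 1L]
      off <<- off + k
      out
    })
  }
  p <- cfg$planted
  tibble(gene = ids$candidates,
         cx_anchors = take_seq(ids$anchor_genes, p$cx),
         cm_anchors = take_seq(ids$anchor_genes, p$cm),
         sc_anchors = take_seq(ids$anchor_genes, p$sc),
         gt_mets = take_cycle(ids$anchor_mets, p$gt),
         gr_mets = take_cycle(ids$anchor_mets, p$gr))
}

sim_ids <- function(cfg) {
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  n_c <- nrow(cfg$planted)
  list(genes = genes,
       anchor_genes = genes[seq_len(cfg$n_anchor_genes)],
       candidates = genes[cfg$n_anchor_genes + seq_len(n_c)],
       background = genes[-(seq_len(cfg$n_anchor_genes + n_c))],
       mets = sprintf("M%02d", seq_len(cfg$n_metabolites)),
       anchor_mets = sprintf("M%02d", seq_len(cfg$n_anchor_metabolites)))
}

# Gene models on 10 chromosomes, 20-kb spacing (so SNPs in different genes
# on one chromosome are always > 10 kb apart), except the last two genes,
# which are placed ~6 kb apart to host the distance-rule decoy SNP pair.
simulate_gene_models <- function(cfg, ids) {
  n <- cfg$n_genes
  per_chrom <- ceiling(n / 10)
  chrom_i <- ((seq_len(n) - 1L) %/% per_chrom) + 1L
  within <- ((seq_len(n) - 1L) %% per_chrom) + 1L
  start <- 1L + (within - 1L) * 20000L
  genes <- tibble(gene_id = ids$genes,
                  chrom = sprintf("Chr%02d", chrom_i),
                  start = start, end = start + 3999L, strand = "+")
  genes$chrom[n] <- genes$chrom[n - 1L]
  genes$start[n] <- genes$end[n - 1L] + 3001L
  genes$end[n] <- genes$start[n] + 3999L
  genes
}

sim_expression <- function(cfg, ids, planted, seed) {
  blocks <- planted |>
    filter(lengths(.data$cx_anchors) > 0)
  blocks <- map2(blocks$gene, blocks$cx_anchors, ~c(.x, .y))
  simulate_block_matrix(ids$genes, cfg$n_samples_expr, blocks,
                        target_rho = cfg$target_rho,
                        clean_threshold = cfg$coexpr_threshold, seed = seed)
}

sim_methylation <- function(cfg, ids, planted, seed) {
  blocks <- planted |>
    filter(lengths(.data$cm_anchors) > 0)
  blocks <- map2(blocks$gene, blocks$cm_anchors, ~c(.x, .y))
  simulate_block_matrix(ids$genes, cfg$n_samples_meth, blocks,
                        exact_ranks = TRUE,
                        clean_threshold = cfg$cometh_threshold, seed = seed)
}

# Genotypes: planted co-segregating SNP pairs (balanced homozygous pattern
# copied with per-sample flips) across gene pairs that satisfy the distance
# rule, a decoy pair < 10 kb apart, per-edge GWAS tag SNPs inside candidate
# genes, and background SNPs. Verified: planted pairs reach ccc_min, no
# unplanned qualifying pair does.
sim_genotypes <- function(cfg, ids, planted, genes, seed, max_iter = 30) {
  n <- cfg$n_samples_geno
  flip <- function(pattern) {
    fl <- stats::runif(n) < cfg$ld_flip_prob
    ifelse(fl, 2L - pattern, pattern)
  }
  # exactly balanced homozygous pattern: the CCC of an unflipped copy is 1
  balanced_pattern <- function() sample(rep(c(0L, 2L), length.out = n))
  bg_dosage <- function() {
    stats::rbinom(n, 2L, stats::runif(1, 0.15, 0.4))
  }
  withr::with_seed(as.integer(seed), {
    rows <- list()   # each: snp_id, gene_id, type, pair_id, dosage
    add <- function(gene_id, type, pair_id, dosage) {
      rows[[length(rows) + 1L]] <<- list(gene_id = gene_id, type = type,
                                         pair_id = pair_id, dosage = dosage)
    }
    pair_id <- 0L
    for (i in seq_len(nrow(planted))) {
      for (a in planted$sc_anchors[[i]]) {
        pair_id <- pair_id + 1L
        pattern <- balanced_pattern()
        add(planted$gene[i], "sc", pair_id, flip(pattern))
        add(a, "sc", pair_id, flip(pattern))
      }
      for (m in planted$gt_mets[[i]]) {
        add(planted$gene[i], "gt", NA_integer_, bg_dosage())
      }
    }
    decoy_genes <- utils::tail(genes$gene_id, 2)
    decoy_pattern <- balanced_pattern()
    add(decoy_genes[1], "decoy", -1L, decoy_pattern)
    add(decoy_genes[2], "decoy", -1L, decoy_pattern)
    bg_pool <- setdiff(ids$background, decoy_genes)
    bg_genes <- sample(bg_pool, cfg$n_background_snps)
    for (g in bg_genes) add(g, "background", NA_integer_, bg_dosage())

    info <- tibble(gene_id = map_chr(rows, "gene_id"),
                   type = map_chr(rows, "type"),
                   pair_id = map_int(rows, "pair_id"))
    info$snp_id <- sprintf("snp%03d", seq_len(nrow(info)))
    # place SNPs inside their gene, offset so positions stay unique
    info <- info |>
      left_join(genes, by = "gene_id") |>
      group_by(.data$gene_id) |>
      mutate(pos = .data$start + 100L * row_number()) |>
      ungroup()
    dos <- do.call(rbind, lapply(rows, function(r) r$dosage))
    dimnames(dos) <- list(info$snp_id, sprintf("s%03d", seq_len(n)))

    qualifies <- function(i, j) {
      info$gene_id[i] != info$gene_id[j] &&
        (info$chrom[i] != info$chrom[j] ||
           abs(info$pos[i] - info$pos[j]) > cfg$min_dist_bp)
    }
    planted_pair <- outer(info$pair_id, info$pair_id,
                          function(a, b) !is.na(a) & !is.na(b) & a == b)
    for (iter in seq_len(max_iter)) {
      cm <- ccc_matrix(dos)
      ok <- TRUE
      idx <- which(upper.tri(cm), arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        if (planted_pair[i, j]) {
          if (info$type[i] == "sc" && cm[i, j] < cfg$ccc_min) {
            # re-flip the pair from a fresh pattern
            pattern <- balanced_pattern()
            dos[i, ] <- flip(pattern); dos[j, ] <- flip(pattern)
            ok <- FALSE
          }
        } else if (cm[i, j] >= cfg$ccc_min && qualifies(i, j)) {
          # spurious qualifying pair: redraw the most expendable member
          tgt <- if (info$type[j] %in% c("background", "gt")) j
                 else if (info$type[i] %in% c("background", "gt")) i else j
          dos[tgt, ] <- if (info$type[tgt] %in% c("background", "gt")) bg_dosage()
                        else flip(balanced_pattern())
          ok <- FALSE
        }
      }
      if (ok) break
      if (iter == max_iter) abort("genotype world failed to stabilize")
    }
    genotype_matrix(dos, tibble(snp_id = info$snp_id, chrom = info$chrom,
                                pos = info$pos))
  })
}

sim_associations <- function(cfg, ids, planted, geno_meta, snp_types, seed) {
  withr::with_seed(as.integer(seed), {
    rows <- list()
    gt_snps <- geno_meta$snp_id[snp_types == "gt"]
    k <- 0L
    for (i in seq_len(nrow(planted))) {
      for (m in planted$gt_mets[[i]]) {
        k <- k + 1L
        rows[[length(rows) + 1L]] <- tibble(
          unit_id = gt_snps[k], phenotype_id = m,
          p_value = cfg$assoc_p_planted, layer_tag = "gwas_traditional")
      }
      for (m in planted$gr_mets[[i]]) {
        rows[[length(rows) + 1L]] <- tibble(
          unit_id = planted$gene[i], phenotype_id = m,
          p_value = cfg$assoc_p_planted, layer_tag = "gwas_rare")
      }
    }
    bg_mets <- setdiff(ids$mets, ids$anchor_mets)
    bg_snps <- geno_meta$snp_id[snp_types == "background"]
    nb <- cfg$n_background_assoc
    rows[[length(rows) + 1L]] <- tibble(
      unit_id = sample(bg_snps, nb, replace = TRUE),
      phenotype_id = sample(bg_mets, nb, replace = TRUE),
      p_value = stats::runif(nb), layer_tag = "gwas_traditional")
    rows[[length(rows) + 1L]] <- tibble(
      unit_id = sample(ids$background, nb, replace = TRUE),
      phenotype_id = sample(bg_mets, nb, replace = TRUE),
      p_value = stats::runif(nb), layer_tag = "gwas_rare")
    out <- bind_rows(rows)
    out$q_value <- NA_real_
    distinct(out, .data$unit_id, .data$phenotype_id, .data$layer_tag,
             .keep_all = TRUE)[
      c("unit_id", "phenotype_id", "p_value", "q_value", "layer_tag")]
  })
}

sim_go <- function(cfg, ids, planted, seed) {
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (i in seq_len(nrow(planted))) {
      partners <- unique(c(planted$cx_anchors[[i]], planted$cm_anchors[[i]],
                           planted$sc_anchors[[i]]))
      size <- sample(seq(cfg$go_term_size_range[1],
                         cfg$go_term_size_range[2]), 1)
      members <- c(planted$gene[i], partners)
      if (length(members) < size) {
        pad <- setdiff(ids$anchor_genes, members)
        members <- c(members, utils::head(pad, size - length(members)))
      }
      members <- utils::head(members, max(size, 2))
      rows[[i]] <- tibble(gene = members, term = sprintf("GO:P%03d", i))
    }
    for (b in seq_len(cfg$n_background_terms)) {
      members <- sample(ids$background, cfg$background_term_size)
      rows[[length(rows) + 1L]] <- tibble(
        gene = members, term = sprintf("GO:B%03d", b))
    }
    distinct(bind_rows(rows))
  })
}

# Ground truth implied by the planted design: per-candidate depths, breadth,
# discounted depth, high-LOE membership (breadth >= 3 plus >= 1 GWAS edge)
# and tier, computed directly from the design counts.
sim_ground_truth <- function(cfg, planted) {
  d <- cfg$planted
  gt <- tibble(gene = planted$gene,
               depth_coexpression = d$cx,
               depth_comethylation = d$cm,
               depth_snp_correlation = d$sc,
               depth_gwas_traditional = d$gt,
               depth_gwas_rare = d$gr)
  dm <- as.matrix(gt[-1])
  gt$breadth <- as.integer(rowSums(dm > 0))
  gt$depth_total <- as.integer(rowSums(dm))
  gt$depth_minus_cometh <- gt$depth_total - gt$depth_comethylation
  gt$high_loe <- gt$breadth >= 3 & (d$gt + d$gr) >= 1
  gt$tier <- ifelse(!gt$high_loe, NA_integer_,
             ifelse(gt$breadth >= 4 | gt$depth_minus_cometh >= 5, 1L,
             ifelse(gt$depth_minus_cometh == 4, 2L, 3L)))
  gt
}

#' Simulate a complete multi-omic world
#'
#' Generates expression, methylation, genotypes, gene models, association
#' tables, anchor sets and GO annotations consistent with a planted design,
#' together with the ground truth the design implies.
#'
#' @param cfg An [loe_sim_config()].
#' @param seed Integer seed; per-component seeds are derived from it, so the
#'   same seed yields a byte-identical world.
#' @return List of class `loe_world`: `config`, `seed`, `ids`, `anchors`,
#'   `expression`, `methylation`, `genotypes`, `gene_models`,
#'   `associations`, `go_annotation`, `planted`, `ground_truth`.
#' @export
simulate_world <- function(cfg = loe_sim_config(), seed = 1) {
  ids <- sim_ids(cfg)
  planted <- assign_partners(cfg, ids)
  genes <- simulate_gene_models(cfg, ids)
  geno <- sim_genotypes(cfg, ids, planted, genes, derive_seed(seed, "geno"))
  snp_types <- sim_snp_types(cfg, planted)
  world <- list(
    config = cfg, seed = seed, ids = ids,
    anchors = anchor_set(ids$anchor_genes, ids$anchor_mets),
    expression = sim_expression(cfg, ids, planted, derive_seed(seed, "expr")),
    methylation = sim_methylation(cfg, ids, planted, derive_seed(seed, "meth")),
    genotypes = geno,
    gene_models = genes,
    associations = sim_associations(cfg, ids, planted, geno$meta, snp_types,
                                    derive_seed(seed, "assoc")),
    go_annotation = sim_go(cfg, ids, planted, derive_seed(seed, "go")),
    planted = planted)
  world$ground_truth <- sim_ground_truth(cfg, planted)
  class(world) <- "loe_world"
  world
}

# SNP type labels in the same order sim_genotypes emits rows.
sim_snp_types <- function(cfg, planted) {
  types <- character()
  for (i in seq_len(nrow(planted))) {
    types <- c(types, rep("sc", 2L * length(planted$sc_anchors[[i]])),
               rep("gt", length(planted$gt_mets[[i]])))
  }
  c(types, "decoy", "decoy", rep("background", cfg$n_background_snps))
}

#' Write a simulated world to disk
#'
#' Emits every format the readers accept (matrix TSVs, genotype TSV,
#' GFF-lite gene table, association TSV, anchor lists, GO annotation TSV)
#' plus a JSON manifest carrying the ground truth for assertions.
#'
#' @param world An `loe_world` from [simulate_world()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
emit_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_omics_matrix(world$expression, p("expression.tsv"))
  write_omics_matrix(world$methylation, p("methylation.tsv"))
  write_genotypes(world$genotypes, p("genotypes.tsv"))
  write_gene_models(world$gene_models, p("gene_models.tsv"))
  write_associations(world$associations, p("associations.tsv"))
  write_anchor_set(world$anchors, p("anchor_genes.txt"), p("anchor_metabolites.txt"))
  write_go_annotations(world$go_annotation, p("go_annotations.tsv"))
  manifest <- list(seed = world$seed,
                   n_genes = world$config$n_genes,
                   high_loe = world$ground_truth$gene[world$ground_truth$high_loe],
                   ground_truth = world$ground_truth)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  files <- list(expression = p("expression.tsv"), methylation = p("methylation.tsv"),
                genotypes = p("genotypes.tsv"), gene_models = p("gene_models.tsv"),
                associations = p("associations.tsv"),
                anchor_genes = p("anchor_genes.txt"),
                anchor_metabolites = p("anchor_metabolites.txt"),
                go_annotations = p("go_annotations.tsv"),
                manifest = p("manifest.json"))
  invisible(files)
}
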