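# Construction of the per-omics LOE input layers.

#' Build a Spearman correlation layer
#'
#' All-pairs Spearman rank correlation over the sample vectors of a
#' feature x sample matrix; edges are kept where `|rho| >= threshold`,
#' with `weight = rho` and the sign of the correlation as the edge sign.
#' Ties are handled with average ranks. Zero-variance features have no
#' defined correlation and are excluded (reported with a message).
#'
#' @param m Feature x sample numeric matrix (TPM).
#' @param threshold Absolute correlation threshold in (0, 1]; 0.85 for the
#'   coexpression layer and 0.95 for the comethylation layer.
#' @param layer_name Layer label, e.g. `"coexpression"`.
#' @return An `loe_network` of gene-gene edges.
#' @export
build_correlation_layer <- function(m, threshold, layer_name = "coexpression") {
  assert_matrix(m)
  if (ncol(m) < 3) abort("need at least 3 samples")
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  constant <- apply(m, 1, function(x) length(unique(x)) == 1)
  if (any(constant)) {
    inform(sprintf("excluding %d zero-variance feature(s) from %s",
                   sum(constant), layer_name))
    m <- m[!constant, , drop = FALSE]
  }
  if (nrow(m) < 2) return(loe_network(tibble(), layer = NULL))
  rho <- stats::cor(t(m), method = "spearman")
  idx <- which(upper.tri(rho) & abs(rho) >= threshold, arr.ind = TRUE)
  loe_network(tibble(node_a = rownames(rho)[idx[, 1]],
                     node_b = rownames(rho)[idx[, 2]],
                     weight = rho[idx],
                     sign = ifelse(rho[idx] < 0, "-", "+")),
              layer = layer_name)
}

#' Custom correlation coefficient between two SNP dosage vectors
#'
#' A co-segregation measure on biallelic genotypes. Each sample's dosage is
#' expanded into its two alleles; for the pair of SNPs the 2 x 2 allele
#' co-occurrence table \eqn{n_{rs}} (r, s over ref/alt) is accumulated across
#' the pairwise-complete samples, and each table entry is scored
#' \deqn{t_{rs} = \tfrac{9}{2} f_{rs} (1 - \tfrac{2}{3} f_r)(1 - \tfrac{2}{3} f_s)}
#' with \eqn{f_{rs} = n_{rs}/4n}, \eqn{f_r} the allele frequency at the first
#' SNP, and \eqn{f_s} at the second. The CCC is the maximum entry score. It is
#' symmetric, lies in `[0, 1]`, and attains 1 exactly for balanced,
#' perfectly co-segregating homozygous allele patterns.
#'
#' @param a,b Integer dosage vectors over \{0, 1, 2, NA\}, equal length;
#'   missing entries are excluded pairwise.
#' @return CCC in `[0, 1]`, or `NA` with a warning when fewer than 2
#'   informative samples remain.
#' @export
#' @examples
#' ccc(c(0, 0, 2, 2), c(0, 0, 2, 2))  # 1: balanced homozygous co-segregation
ccc <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) {
    warn("fewer than 2 informative samples; CCC undefined")
    return(NA_real_)
  }
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  alt_a <- a; ref_a <- 2 - a
  alt_b <- b; ref_b <- 2 - b
  n_rs <- c(rr = sum(ref_a * ref_b), ra = sum(ref_a * alt_b),
            ar = sum(alt_a * ref_b), aa = sum(alt_a * alt_b))
  f_rs <- n_rs / (4 * n)
  f_a <- c(r = sum(ref_a), a = sum(alt_a)) / (2 * n)
  f_b <- c(r = sum(ref_b), a = sum(alt_b)) / (2 * n)
  fa_rs <- f_a[c("r", "r", "a", "a")]
  fb_rs <- f_b[c("r", "a", "r", "a")]
  entries <- 4.5 * f_rs * (1 - (2 / 3) * fa_rs) * (1 - (2 / 3) * fb_rs)
  max(0, min(1, max(entries)))
}

# All-pairs CCC matrix. Fast matrix-product path when no dosages are
# missing; falls back to the pairwise scalar otherwise.
ccc_matrix <- function(dos) {
  if (!anyNA(dos)) {
    n <- ncol(dos)
    alt <- dos; ref <- 2 - dos
    N <- list(rr = ref %*% t(ref), ra = ref %*% t(alt),
              ar = alt %*% t(ref), aa = alt %*% t(alt))
    f_ref <- rowSums(ref) / (2 * n)
    f_alt <- 1 - f_ref
    sc <- function(nm, fa, fb) {
      4.5 * (N[[nm]] / (4 * n)) *
        outer(1 - (2 / 3) * fa, 1 - (2 / 3) * fb)
    }
    out <- pmax(sc("rr", f_ref, f_ref), sc("ra", f_ref, f_alt),
                sc("ar", f_alt, f_ref), sc("aa", f_alt, f_alt))
    out <- pmin(pmax(out, 0), 1)
  } else {
    k <- nrow(dos)
    out <- matrix(NA_real_, k, k, dimnames = list(rownames(dos), rownames(dos)))
    for (i in seq_len(k)) {
      for (j in i:k) {
        v <- suppressWarnings(ccc(dos[i, ], dos[j, ]))
        out[i, j] <- out[j, i] <- v
      }
    }
  }
  dimnames(out) <- list(rownames(dos), rownames(dos))
  out
}

# Map SNPs to the genes whose [start - flank, end + flank] interval contains
# them (1-based inclusive, both strands). Returns tibble snp_id, gene_id;
# SNPs inside several (overlapping) genes yield one row per gene.
map_snps_to_genes <- function(snp_meta, genes, flank_bp = 0) {
  hits <- inner_join(snp_meta, genes, by = "chrom",
                     relationship = "many-to-many") |>
    filter(.data$pos >= .data$start - flank_bp,
           .data$pos <= .data$end + flank_bp)
  tibble(snp_id = hits$snp_id, gene_id = hits$gene_id)
}

#' Build the SNP co-segregation (CCC) layer
#'
#' Computes the CCC over all SNP pairs, keeps pairs with
#' `ccc >= ccc_min` that are on different chromosomes or more than
#' `min_dist_bp` apart, maps each SNP to the gene containing it, and
#' projects qualifying SNP pairs to gene-gene edges. Multiple SNP pairs
#' hitting the same gene pair collapse to one edge carrying the maximum CCC;
#' pairs where both SNPs sit in the same gene are discarded, as are SNPs
#' located in no gene.
#'
#' @param g A (MAF-filtered) `genotype_matrix`.
#' @param genes Gene model tibble (see [read_gene_models()]).
#' @param ccc_min Minimum CCC (default 0.7).
#' @param min_dist_bp Minimum same-chromosome separation in bp
#'   (default 10000); cross-chromosome pairs always pass.
#' @param pair_fn SNP-SNP association matrix function (defaults to the CCC);
#'   pluggable so e.g. an r-squared measure can be swapped in.
#' @return An `loe_network` with layer `"snp_correlation"`.
#' @export
build_snp_correlation_layer <- function(g, genes, ccc_min = 0.7,
                                        min_dist_bp = 10000,
                                        pair_fn = ccc_matrix) {
  dos <- g$dosages
  meta <- g$meta
  if (nrow(dos) < 2) return(loe_network(tibble()))
  cm <- pair_fn(dos)
  idx <- which(upper.tri(cm) & !is.na(cm) & cm >= ccc_min, arr.ind = TRUE)
  if (nrow(idx) == 0) return(loe_network(tibble()))
  pairs <- tibble(snp_a = meta$snp_id[idx[, 1]], snp_b = meta$snp_id[idx[, 2]],
                  ccc = cm[idx],
                  chrom_a = meta$chrom[idx[, 1]], chrom_b = meta$chrom[idx[, 2]],
                  dist = abs(meta$pos[idx[, 1]] - meta$pos[idx[, 2]])) |>
    filter(.data$chrom_a != .data$chrom_b | .data$dist > min_dist_bp)
  if (nrow(pairs) == 0) return(loe_network(tibble()))
  s2g <- map_snps_to_genes(meta, genes)
  edges <- pairs |>
    inner_join(s2g, by = c(snp_a = "snp_id"), relationship = "many-to-many") |>
    rename(gene_a = "gene_id") |>
    inner_join(s2g, by = c(snp_b = "snp_id"), relationship = "many-to-many") |>
    rename(gene_b = "gene_id") |>
    filter(.data$gene_a != .data$gene_b) |>
    mutate(node_a = pmin(.data$gene_a, .data$gene_b),
           node_b = pmax(.data$gene_a, .data$gene_b)) |>
    group_by(.data$node_a, .data$node_b) |>
    summarise(weight = max(.data$ccc), .groups = "drop") |>
    mutate(sign = "n/a")
  loe_network(edges, layer = "snp_correlation")
}

#' Build a GWAS / eQTN association layer
#'
#' SNP-level rows are mapped to the genes whose
#' `[start - flank_bp, end + flank_bp]` interval contains the SNP (flank 0
#' for the traditional single-SNP layer; 2000 bp for rare-variant regions);
#' gene-level rows pass through directly. Rows are filtered to significant
#' associations (`q_value <= q_max` when supplied, otherwise BH on the
#' p-values at `q_max`). Output edges connect genes to namespaced phenotype
#' nodes with `weight = -log10(p)` and sign `"n/a"`; multiple significant
#' units mapping to the same gene-phenotype pair keep the strongest
#' (largest-weight) association.
#'
#' @param assoc Association tibble (see [read_associations()]).
#' @param genes Gene model tibble.
#' @param snp_meta Tibble `snp_id`, `chrom`, `pos` used to place SNP-level
#'   rows (`NULL` if all rows are gene-level).
#' @param flank_bp Flank for SNP-to-gene interval mapping (default 0).
#' @param layer_tag Which `layer_tag` rows to use and the layer label.
#' @param q_max Significance cutoff (default 0.1).
#' @param phenotype_kind `"metabolite"` (phenotype ids get the `met:`
#'   namespace) or `"gene"` (eQTN transcript phenotypes, ids kept as genes).
#' @return An `loe_network` of gene-phenotype edges.
#' @export
build_association_layer <- function(assoc, genes, snp_meta = NULL, flank_bp = 0,
                                    layer_tag = "gwas_traditional", q_max = 0.1,
                                    phenotype_kind = c("metabolite", "gene")) {
  phenotype_kind <- match.arg(phenotype_kind)
  rows <- filter(assoc, .data$layer_tag == .env$layer_tag)
  if (nrow(rows) == 0) return(loe_network(tibble()))
  if (all(is.na(rows$q_value))) {
    rows$q_value <- bh_fdr(rows$p_value, q = q_max)$q_value
  }
  rows <- filter(rows, .data$q_value <= q_max)
  if (nrow(rows) == 0) return(loe_network(tibble()))
  gene_level <- rows$unit_id %in% genes$gene_id
  mapped <- rows[gene_level, ] |> mutate(gene_id = .data$unit_id)
  if (any(!gene_level)) {
    if (is.null(snp_meta)) {
      inform(sprintf("%d non-gene unit(s) dropped (no snp_meta supplied)",
                     sum(!gene_level)))
    } else {
      snp_rows <- rows[!gene_level, ]
      s2g <- map_snps_to_genes(
        filter(snp_meta, .data$snp_id %in% snp_rows$unit_id), genes, flank_bp)
      hit <- inner_join(snp_rows, s2g, by = c(unit_id = "snp_id"),
                        relationship = "many-to-many")
      n_lost <- length(setdiff(snp_rows$unit_id, s2g$snp_id))
      if (n_lost > 0) inform(sprintf("%d SNP(s) mapped to no gene; dropped", n_lost))
      mapped <- bind_rows(mapped, hit)
    }
  }
  if (nrow(mapped) == 0) return(loe_network(tibble()))
  phen <- if (phenotype_kind == "metabolite") met_id(mapped$phenotype_id) else mapped$phenotype_id
  edges <- tibble(gene = mapped$gene_id, phen = phen,
                  weight = -log10(mapped$p_value)) |>
    filter(.data$gene != .data$phen) |>
    mutate(node_a = pmin(.data$gene, .data$phen),
           node_b = pmax(.data$gene, .data$phen)) |>
    group_by(.data$node_a, .data$node_b) |>
    summarise(weight = max(.data$weight), .groups = "drop") |>
    mutate(sign = "n/a")
  loe_network(edges, layer = layer_tag)
}
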