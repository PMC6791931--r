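# Readers and writers for every external representation the pipeline touches:
# feature x sample matrices, genotype tables (TSV or minimal VCF), gene
# coordinate tables (GFF-lite TSV or BED), association tables, anchor lists,
# GO annotations, and networks (Cytoscape-loadable TSV / SIF).

#' Read a feature-by-sample omics matrix
#'
#' Expects a TSV with a header row of sample ids and the feature id in the
#' first column (expression or methylation, TPM or raw counts).
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_omics_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  ids <- df[[1]]
  assert_unique(ids, "feature")
  assert_unique(names(df)[-1], "sample")
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, names(df)[-1]))
  bad <- which(is.na(vals) & !is.na(as.matrix(df[-1])), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric cell at feature '%s', sample '%s'",
                  ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  if (any(is.na(vals))) abort("missing values are not allowed in omics matrices")
  if (any(vals < 0)) abort("omics matrix values must be >= 0")
  rownames(vals) <- ids
  vals
}

#' Write a feature-by-sample omics matrix
#' @param m Numeric matrix with rownames and colnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(m, path) {
  assert_matrix(m)
  df <- tibble(feature_id = rownames(m)) |> bind_cols(as_tibble(m))
  readr::write_tsv(df, path)
  invisible(path)
}

# Tokens treated as a missing genotype call.
MISSING_GT <- c(".", "./.", ".|.", "NA", "")

#' Read a genotype dosage matrix
#'
#' Two dialects: a TSV with columns `snp_id`, `chrom`, `pos` followed by one
#' column per sample holding dosages in \{0, 1, 2\} (missing tokens `.`,
#' `./.`, `NA`), or a minimal VCF whose FORMAT carries only `GT` (parsed with
#' \pkg{vcfR}; genotypes are decoded to alt-allele dosage).
#'
#' @param path Path to the TSV or VCF file.
#' @param format `"auto"` (by extension), `"tsv"`, or `"vcf"`.
#' @return A list of class `genotype_matrix` with elements
#'   `dosages` (SNP x sample integer matrix with `NA` for missing) and
#'   `meta` (tibble `snp_id`, `chrom`, `pos`).
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g) || g %in% MISSING_GT) return(NA_integer_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
    meta <- tibble(snp_id = rownames(gt) %||% vcfR::getID(v),
                   chrom = vcfR::getCHROM(v),
                   pos = as.integer(vcfR::getPOS(v)))
    if (anyNA(meta$snp_id)) {
      meta$snp_id <- paste(meta$chrom, meta$pos, sep = "_")
    }
    rownames(dos) <- meta$snp_id
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(
      .default = readr::col_character()))
    need <- c("snp_id", "chrom", "pos")
    if (!all(need %in% names(df))) {
      abort("genotype TSV needs columns snp_id, chrom, pos before sample columns")
    }
    meta <- tibble(snp_id = df$snp_id, chrom = df$chrom, pos = as.integer(df$pos))
    samp <- setdiff(names(df), need)
    cells <- as.matrix(df[samp])
    cells[cells %in% MISSING_GT] <- NA
    dos <- matrix(suppressWarnings(as.integer(cells)), nrow = nrow(df),
                  dimnames = list(df$snp_id, samp))
    if (any(is.na(dos) & !is.na(cells))) abort("non-numeric genotype cell")
  }
  assert_unique(meta$snp_id, "SNP")
  if (any(meta$pos < 1, na.rm = TRUE)) abort("SNP positions must be >= 1")
  if (!all(dos %in% c(0L, 1L, 2L, NA))) abort("dosages must be 0, 1, 2 or missing")
  genotype_matrix(dos, meta)
}

#' Assemble a genotype matrix object
#' @param dosages SNP x sample matrix over \{0,1,2,NA\}.
#' @param meta Tibble with `snp_id`, `chrom`, `pos` matching the rows.
#' @return A `genotype_matrix` list.
#' @export
genotype_matrix <- function(dosages, meta) {
  stopifnot(nrow(dosages) == nrow(meta), all(rownames(dosages) == meta$snp_id))
  meta <- as_tibble(meta)
  meta$pos <- as.integer(meta$pos)
  structure(list(dosages = dosages, meta = meta), class = "genotype_matrix")
}

#' Write a genotype matrix in the TSV dialect
#' @param g A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  dos <- g$dosages
  cells <- apply(dos, 2, function(x) ifelse(is.na(x), ".", as.character(x)))
  df <- bind_cols(g$meta[c("snp_id", "chrom", "pos")],
                  as_tibble(matrix(cells, nrow = nrow(dos),
                                   dimnames = dimnames(dos))))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read gene models (coordinates)
#'
#' GFF-lite dialect: TSV with columns `gene_id`, `chrom`, `start`, `end`,
#' optional `strand`, 1-based inclusive. BED dialect: standard 0-based
#' half-open intervals, converted to 1-based inclusive on read (the
#' conversion is reported with a message).
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"tsv"`, or `"bed"`.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.bed$", path)) "bed" else "tsv"
  if (format == "bed") {
    df <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols())
    out <- tibble(gene_id = as.character(df[[4]]), chrom = as.character(df[[1]]),
                  start = as.integer(df[[2]]) + 1L, end = as.integer(df[[3]]),
                  strand = if (ncol(df) >= 6) as.character(df[[6]]) else "unknown")
    inform("BED intervals converted from 0-based half-open to 1-based inclusive")
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols())
    out <- tibble(gene_id = as.character(df$gene_id), chrom = as.character(df$chrom),
                  start = as.integer(df$start), end = as.integer(df$end),
                  strand = if ("strand" %in% names(df)) as.character(df$strand) else "unknown")
  }
  assert_unique(out$gene_id, "gene")
  if (any(out$start > out$end)) abort("gene start must be <= end")
  out
}

#' Write gene models in the GFF-lite TSV dialect
#' @param genes Tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  readr::write_tsv(genes[c("gene_id", "chrom", "start", "end", "strand")], path)
  invisible(path)
}

ASSOC_TAGS <- c("gwas_traditional", "gwas_rare", "eqtn")

#' Read an association table
#'
#' TSV with columns `unit_id` (SNP or gene), `phenotype_id`, `p_value`,
#' optional `q_value`, and `layer_tag` in
#' \{`gwas_traditional`, `gwas_rare`, `eqtn`\}.
#'
#' @param path Input path.
#' @return Validated tibble.
#' @export
read_associations <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols())
  need <- c("unit_id", "phenotype_id", "p_value", "layer_tag")
  if (!all(need %in% names(df))) {
    abort(sprintf("association table needs columns: %s", paste(need, collapse = ", ")))
  }
  if (!"q_value" %in% names(df)) df$q_value <- NA_real_
  df$q_value <- as.numeric(df$q_value)
  out <- as_tibble(df)[c("unit_id", "phenotype_id", "p_value", "q_value", "layer_tag")]
  if (any(is.na(out$p_value)) || any(out$p_value <= 0 | out$p_value > 1)) {
    abort("p_value must be present and in (0, 1] for every row")
  }
  if (!all(out$layer_tag %in% ASSOC_TAGS)) {
    abort(sprintf("layer_tag must be one of: %s", paste(ASSOC_TAGS, collapse = ", ")))
  }
  out
}

#' Write an association table
#' @param assoc Association tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  readr::write_tsv(assoc, path)
  invisible(path)
}

#' Construct an anchor set
#'
#' @param genes Character vector of anchor gene ids.
#' @param metabolites Character vector of anchor metabolite ids (namespaced
#'   with `met:` on ingest).
#' @return List of class `anchor_set` with `genes` and `metabolites`.
#' @export
anchor_set <- function(genes = character(), metabolites = character()) {
  genes <- unique(as.character(genes))
  metabolites <- met_id(unique(as.character(metabolites)))
  if (length(genes) + length(metabolites) == 0) abort("anchor set must be non-empty")
  if (length(intersect(genes, metabolites)) > 0) abort("anchor genes and metabolites must be disjoint")
  structure(list(genes = genes, metabolites = metabolites), class = "anchor_set")
}

#' All anchor node ids (genes + namespaced metabolites)
#' @param anchors An `anchor_set`.
#' @return Character vector.
#' @export
anchor_nodes <- function(anchors) c(anchors$genes, anchors$metabolites)

#' Read anchor gene and metabolite lists (one id per line)
#' @param gene_path Path to the anchor gene list (or `NULL`).
#' @param metabolite_path Path to the anchor metabolite list (or `NULL`).
#' @return An `anchor_set`.
#' @export
read_anchor_set <- function(gene_path = NULL, metabolite_path = NULL) {
  rd <- function(p) if (is.null(p)) character() else readr::read_lines(p, skip_empty_rows = TRUE)
  anchor_set(rd(gene_path), rd(metabolite_path))
}

#' Write anchor lists
#' @param anchors An `anchor_set`.
#' @param gene_path,metabolite_path Output paths.
#' @return Invisibly, `NULL`.
#' @export
write_anchor_set <- function(anchors, gene_path, metabolite_path) {
  readr::write_lines(anchors$genes, gene_path)
  readr::write_lines(sub("^met:", "", anchors$metabolites), metabolite_path)
  invisible(NULL)
}

#' Read gene-to-GO-term annotations (two-column TSV: gene, term)
#' @param path Input path.
#' @return Tibble `gene`, `term` (distinct rows).
#' @export
read_go_annotations <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  names(df)[1:2] <- c("gene", "term")
  distinct(as_tibble(df[1:2]))
}

#' Write gene-to-GO-term annotations
#' @param ann Tibble `gene`, `term`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_go_annotations <- function(ann, path) {
  readr::write_tsv(ann[c("gene", "term")], path)
  invisible(path)
}

#' Write a network to disk
#'
#' TSV dialect: columns `node_a`, `node_b`, `layer_name`, `weight`, `sign`,
#' one row per edge in canonical order; round-trips losslessly through
#' [read_network()]. SIF dialect (Cytoscape): `node_a <layer_name> node_b`.
#'
#' @param net An `loe_network`.
#' @param path Output path.
#' @param dialect `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  net <- loe_network(as_tibble(net))  # re-canonicalize defensively
  if (dialect == "tsv") {
    df <- tibble(node_a = net$node_a, node_b = net$node_b,
                 layer_name = net$layer, weight = net$weight, sign = net$sign)
    readr::write_tsv(df, path)
  } else {
    readr::write_lines(sprintf("%s\t%s\t%s", net$node_a, net$layer, net$node_b), path)
  }
  invisible(path)
}

#' Read a network written in the TSV dialect
#' @param path Input path.
#' @return An `loe_network`.
#' @export
read_network <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  # base-R numeric parsing is correctly rounded, so write -> read -> write
  # is byte-identical
  loe_network(tibble(node_a = df$node_a, node_b = df$node_b,
                     layer = df$layer_name, weight = as.numeric(df$weight),
                     sign = df$sign))
}

#' Convert raw counts to TPM
#'
#' Per sample column, `TPM_i = 1e6 * (c_i / l_i) / sum_j (c_j / l_j)`, so each
#' non-degenerate sample column sums to one million.
#'
#' @param counts Feature x sample matrix of non-negative counts.
#' @param lengths Named numeric vector of feature lengths in bp (> 0),
#'   covering every feature of `counts`.
#' @return Matrix of TPM values with the same dimnames.
#' @export
#' @examples
#' m <- matrix(c(10, 20), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' tpm_from_counts(m, c(g1 = 1000, g2 = 2000))
tpm_from_counts <- function(counts, lengths) {
  assert_matrix(counts, "counts")
  if (any(counts < 0)) abort("counts must be >= 0")
  if (!all(rownames(counts) %in% names(lengths))) {
    abort("lengths must cover every feature in counts")
  }
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) abort("feature lengths must be > 0")
  rate <- counts / len
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warn(sprintf("%d all-zero sample column(s) left as zeros", sum(zero)))
    tot[zero] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}
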