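# End-to-end orchestration: read inputs, build layers, score, merge, rank,
# filter, validate, and write artifacts.

#' Pipeline configuration
#'
#' Input paths plus every tunable threshold, with defaults set to the
#' pipeline's reference values: coexpression 0.85, comethylation 0.95,
#' CCC 0.7 beyond 10 kb, MAF 0.01, FDR 0.1 (second-round eQTN level
#' 5.1e-4), phenotype MAD cutoff 6, expression-phenotype MAD cutoff 5 with
#' 20% retention, GO term-size cap 1000, breadth threshold 3, 100 shuffles
#' of 100,000 subsampled correlations, 100 randomized networks.
#'
#' @param expression,methylation,genotypes,gene_models,associations Input
#'   paths (`NULL` to skip a layer).
#' @param anchor_genes,anchor_metabolites Anchor list paths.
#' @param go_annotations GO annotation path (`NULL` to skip GO validation).
#' @param exclusion Path to a known-gene exclusion list (`NULL` for none).
#' @param out_dir Output directory.
#' @param coexpr_threshold,cometh_threshold,ccc_min,min_dist_bp,min_maf,max_missing,fdr_q,q2,mad_k,mad_expr,retain_frac,flank_traditional,flank_rare,max_term_size,min_breadth,require_gwas
#'   Thresholds (see description).
#' @param n_shuffles,n_subsample,n_random_networks Validation sizes.
#' @param validate Character vector among `"shuffle"`, `"go"` (default both
#'   when the needed inputs are present; `character()` disables validation).
#' @param seed Global seed; per-stage seeds are derived by stable hashing of
#'   stage names so every stage is independently reproducible.
#' @return A list of class `loe_pipeline_config`.
#' @export
loe_pipeline_config <- function(expression, anchor_genes,
                                methylation = NULL, genotypes = NULL,
                                gene_models = NULL, associations = NULL,
                                anchor_metabolites = NULL,
                                go_annotations = NULL, exclusion = NULL,
                                out_dir = tempfile("loe_out_"),
                                coexpr_threshold = 0.85, cometh_threshold = 0.95,
                                ccc_min = 0.7, min_dist_bp = 10000,
                                min_maf = 0.01, max_missing = 1,
                                fdr_q = 0.1, q2 = 5.1e-4,
                                mad_k = 6, mad_expr = 5.0, retain_frac = 0.2,
                                flank_traditional = 0, flank_rare = 2000,
                                max_term_size = 1000,
                                min_breadth = 3, require_gwas = TRUE,
                                n_shuffles = 100, n_subsample = 100000,
                                n_random_networks = 100,
                                validate = c("shuffle", "go"), seed = 1) {
  cfg <- as.list(environment())
  stopifnot(coexpr_threshold > 0, coexpr_threshold <= 1,
            cometh_threshold > 0, cometh_threshold <= 1,
            ccc_min >= 0, ccc_min <= 1, min_dist_bp >= 0,
            min_maf >= 0, min_maf <= 0.5, fdr_q > 0, fdr_q < 1, q2 < 1,
            min_breadth >= 1)
  structure(cfg, class = "loe_pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the
#' [loe_pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `loe_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(loe_pipeline_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  do.call(loe_pipeline_config, vals)
}

#' Run the full LOE pipeline
#'
#' Executes build-layers, 1-hop extraction, scoring, threshold + merge, tier
#' ranking, known-gene filtering and the requested validations, writing the
#' score table, merged network (TSV and SIF), tier list, validation
#' summaries and a provenance log to `out_dir`.
#'
#' @param config An [loe_pipeline_config()], or a path to a YAML file.
#' @return Invisibly, a list with `layers`, `one_hops`, `scores`, `merge`,
#'   `tiers`, `filtered`, `validation` and `files`.
#' @export
run_loe_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "loe_pipeline_config"))
  cfg <- config
  for (key in c("expression", "anchor_genes")) {
    if (!file.exists(cfg[[key]])) {
      abort(sprintf("stage io_formats: input '%s' not found at %s", key, cfg[[key]]))
    }
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s failed: %s", stage, conditionMessage(e)))
    })
  }
  anchors <- run_stage("io_formats", read_anchor_set(cfg$anchor_genes, cfg$anchor_metabolites))
  expr_m <- run_stage("io_formats", read_omics_matrix(cfg$expression))
  universe <- rownames(expr_m)
  layers <- list()
  layers$coexpression <- run_stage("layer_builders",
    build_correlation_layer(expr_m, cfg$coexpr_threshold, "coexpression"))
  meth_m <- NULL
  if (!is.null(cfg$methylation)) {
    meth_m <- run_stage("io_formats", read_omics_matrix(cfg$methylation))
    universe <- union(universe, rownames(meth_m))
    layers$comethylation <- run_stage("layer_builders",
      build_correlation_layer(meth_m, cfg$cometh_threshold, "comethylation"))
  }
  genes <- if (!is.null(cfg$gene_models))
    run_stage("io_formats", read_gene_models(cfg$gene_models)) else NULL
  if (!is.null(genes)) universe <- union(universe, genes$gene_id)
  geno <- NULL
  if (!is.null(cfg$genotypes) && !is.null(genes)) {
    geno <- run_stage("io_formats", read_genotypes(cfg$genotypes))
    geno <- run_stage("phenotype_prep",
      maf_filter(geno, min_maf = cfg$min_maf, max_missing = cfg$max_missing))
    layers$snp_correlation <- run_stage("layer_builders",
      build_snp_correlation_layer(geno, genes, ccc_min = cfg$ccc_min,
                                  min_dist_bp = cfg$min_dist_bp))
  }
  if (!is.null(cfg$associations) && !is.null(genes)) {
    assoc <- run_stage("io_formats", read_associations(cfg$associations))
    snp_meta <- if (!is.null(geno)) geno$meta else NULL
    layers$gwas_traditional <- run_stage("layer_builders",
      build_association_layer(assoc, genes, snp_meta,
                              flank_bp = cfg$flank_traditional,
                              layer_tag = "gwas_traditional", q_max = cfg$fdr_q))
    layers$gwas_rare <- run_stage("layer_builders",
      build_association_layer(assoc, genes, snp_meta,
                              flank_bp = cfg$flank_rare,
                              layer_tag = "gwas_rare", q_max = cfg$fdr_q))
  }
  one_hops <- run_stage("loe_core",
    lapply(layers, extract_one_hop, anchors = anchors))
  scores <- run_stage("loe_core",
    compute_loe_scores(one_hops, anchors, universe = universe))
  merge <- run_stage("loe_core",
    threshold_and_merge(one_hops, scores, min_breadth = cfg$min_breadth,
                        require_gwas = cfg$require_gwas))
  tiers <- run_stage("loe_core", rank_tiers(scores, merge$high_loe))
  exclusion <- if (!is.null(cfg$exclusion))
    readr::read_lines(cfg$exclusion, skip_empty_rows = TRUE) else character()
  filtered <- run_stage("loe_core", filter_known(tiers, exclusion))

  validation <- list()
  if ("shuffle" %in% cfg$validate) {
    validation$shuffle_expression <- run_stage("validation",
      validate_shuffle(expr_m, threshold = cfg$coexpr_threshold,
                       n_shuffles = cfg$n_shuffles,
                       n_subsample = cfg$n_subsample,
                       seed = derive_seed(cfg$seed, "shuffle_expr")))
    if (!is.null(meth_m)) {
      validation$shuffle_methylation <- run_stage("validation",
        validate_shuffle(meth_m, threshold = cfg$cometh_threshold,
                         n_shuffles = cfg$n_shuffles,
                         n_subsample = cfg$n_subsample,
                         seed = derive_seed(cfg$seed, "shuffle_meth")))
    }
  }
  if ("go" %in% cfg$validate && !is.null(cfg$go_annotations)) {
    ann <- run_stage("io_formats", read_go_annotations(cfg$go_annotations))
    go_net <- run_stage("validation",
      build_go_network(ann, max_term_size = cfg$max_term_size))
    validation$go <- run_stage("validation",
      validate_go_network(one_hops, anchors, go_net, universe,
                          n_random = cfg$n_random_networks,
                          min_breadth = cfg$min_breadth,
                          require_gwas = cfg$require_gwas,
                          seed = derive_seed(cfg$seed, "go")))
  }

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  score_out <- as_tibble(scores) |>
    left_join(select(as_tibble(tiers), "gene", "tier"), by = "gene")
  readr::write_tsv(score_out, p("loe_scores.tsv"))
  write_network(merge$network, p("merged_network.tsv"), "tsv")
  write_network(merge$network, p("merged_network.sif"), "sif")
  readr::write_tsv(as_tibble(filtered), p("tier_candidates.tsv"))
  readr::write_lines(merge$high_loe, p("high_loe_genes.txt"))
  if (length(validation) > 0) {
    summaries <- lapply(validation, function(v) {
      if (inherits(v, "loe_null")) {
        v[c("observed", "n", "null_min", "null_max", "null_mean", "p_value")]
      } else {
        v[c("statistic", "p_value", "threshold", "frac_observed",
            "frac_shuffled", "n_shuffles", "n_subsample")]
      }
    })
    jsonlite::write_json(summaries, p("validation_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  provenance <- list(
    package_version = as.character(utils::packageVersion("loescore")),
    r_version = R.version.string, seed = cfg$seed,
    config = cfg[!vapply(cfg, is.null, logical(1))],
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(provenance, p("provenance.json"), auto_unbox = TRUE,
                       force = TRUE)
  invisible(list(layers = layers, one_hops = one_hops, scores = scores,
                 merge = merge, tiers = tiers, filtered = filtered,
                 validation = validation, out_dir = cfg$out_dir))
}
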