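Package: loescore
Title: Multi-Omic Lines-of-Evidence Networks for Candidate Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-omics-layer networks (Spearman coexpression and
    comethylation, SNP co-segregation via a custom correlation coefficient,
    and metabolite-GWAS association layers), extracts 1-hop neighborhoods
    around a curated anchor set, scores every gene by the breadth and depth
    of its lines of evidence, thresholds and merges layers into a single
    candidate network, and ranks candidates into priority tiers. Includes
    two permutation-based validation procedures (within-gene shuffling of
    omics matrices with rank-sum comparison of correlation pools, and a
    GO-functional-network intersect score compared against label-randomized
    networks), hypergeometric GO enrichment, and a synthetic multi-omic
    world generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
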