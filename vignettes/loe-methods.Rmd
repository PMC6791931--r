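---
title: "Lines-of-evidence scoring across multi-omic networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lines-of-evidence scoring across multi-omic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loescore)
```

## The problem and the method

Regulatory systems such as the woody-plant cell wall involve hundreds of
genes connected through transcriptional, epigenetic and population-genetic
signals, and no single omics assay captures more than a slice of that
architecture. `loescore` implements a lines-of-evidence (LOE) strategy for
candidate-gene prioritization: start from a curated *anchor set* of genes
and metabolite phenotypes with documented roles in the system, represent
each omics data set as an undirected network, and ask which other genes
connect to the anchors through several *independent* kinds of evidence.

Each layer contributes one possible line of evidence:

| layer | nodes | edge rule (default) |
|---|---|---|
| coexpression | gene–gene | Spearman \(|\rho| \ge 0.85\) over 64 expression samples |
| comethylation | gene–gene | Spearman \(|\rho| \ge 0.95\) over 10 methylation samples |
| snp_correlation | gene–gene | CCC \(\ge 0.7\) between SNPs > 10 kb apart, projected to host genes |
| gwas_traditional | gene–metabolite | per-SNP association, BH FDR \(q \le 0.1\), SNP inside the gene body |
| gwas_rare | gene–metabolite | gene-region rare-variant association, BH FDR \(q \le 0.1\), ±2 kb flanks |

From each layer the 1-hop neighborhood of the anchors is extracted (every
edge incident to an anchor, plus its endpoints). For a non-anchor gene
\(g\), the per-layer **depth** \(d_{g\ell}\) counts the distinct anchors
\(g\) touches in layer \(\ell\); the **breadth**
\(b_g = \#\{\ell : d_{g\ell} > 0\}\) counts the evidence types; the total
depth is \(\sum_\ell d_{g\ell}\). Because the comethylation vectors carry
only 10 samples against 64 for expression, chance correlations survive even
a 0.95 cut more easily there, so ranking uses the **comethylation-discounted
depth** \(D_g = \sum_\ell d_{g\ell} - d_{g,\mathrm{cometh}}\): comethylation
still counts toward breadth but not toward the within-breadth ordering.

A gene is **high-LOE** when \(b_g \ge 3\) *and* it has at least one
metabolite-GWAS association (traditional or rare variant) — the GWAS
requirement anchors every candidate to a measurable phenotype. The merged
LOE network is the union of 1-hop edges both of whose endpoints are anchors
or high-LOE genes, each edge labeled with its source layer (so the result
loads directly into Cytoscape from the TSV/SIF writers). High-LOE genes are
ranked into tiers:

* **Tier 1**: \(b_g \ge 4\), or \(b_g = 3\) with \(D_g \ge 5\);
* **Tier 2**: \(b_g = 3\) with \(D_g = 4\);
* **Tier 3**: the rest (\(D_g \le 3\)).

Within tiers the order is (breadth desc, discounted depth desc, gene id
asc); the id tie-break makes output deterministic. Genes already known to
act in the system (the anchor list, or a literature-review exclusion list)
are removed by `filter_known()` so the final table contains genuinely new
candidates. The breadth cutoff of 3 is a parameter; `autoplot()` on the
score table draws the breadth histogram so users can look for an inflection
point of their own data before accepting the default.

## The SNP co-segregation measure

The SNP-correlation layer uses a custom correlation coefficient (CCC)
between biallelic dosage vectors. This package's transcription works on the
allele level: each sample's dosage contributes its two alleles, the
\(2\times2\) allele co-occurrence table \(n_{rs}\) is accumulated over the
pairwise-complete samples (\(\sum_{rs} n_{rs} = 4n\)), and each cell is
scored

\[
t_{rs} = \tfrac{9}{2}\, f_{rs}\,\bigl(1 - \tfrac{2}{3} f_r\bigr)\bigl(1 - \tfrac{2}{3} f_s\bigr),
\qquad f_{rs} = \frac{n_{rs}}{4n},
\]

with \(f_r, f_s\) the marginal allele frequencies; the scalar CCC is the
maximum cell score. Because \(f_{rs} \le \min(f_r, f_s)\), the measure is
provably confined to \([0,1]\); it is symmetric and attains exactly 1 for
balanced, perfectly co-segregating homozygous patterns (the configuration
the simulator plants). Heterozygote-rich identical vectors score lower
(an all-heterozygote pair scores 0.5) — heterozygotes genuinely carry less
co-segregation information at the allele level. The measure is pluggable
(`pair_fn` of `build_snp_correlation_layer()`), so an \(r^2\)-style LD
statistic can be swapped in for sensitivity analysis. Missing genotypes are
excluded pairwise rather than imputed, consistent with filtering SNPs on
call rate upstream; `maf_filter()` recomputes MAF from dosages and applies
the MAF \(\ge 0.01\) and missingness cuts.

Projection to genes: a SNP belongs to a gene when its position falls inside
the gene body (1-based inclusive, both strands — no strand rule is defined
for this lookup). SNP pairs must be on different chromosomes or more than
10 kb apart (an LD guard; cross-chromosome pairs always pass since physical
distance is meaningless there). Several qualifying SNP pairs hitting one
gene pair collapse to a single edge keeping the maximum CCC — the strongest
evidence, and an order-independent choice.

## Phenotype cleaning and multiple testing

Metabolite phenotypes are screened with an **unscaled** median absolute
deviation: MAD \(= \mathrm{median}\,|x - \mathrm{median}(x)|\), no 1.4826
consistency constant, because the rule is stated directly in "MADs from the
median" (default cutoff 6). If the MAD is zero the threshold is undefined;
nothing is masked and a warning is raised rather than discarding a
near-constant phenotype wholesale. The filter is affine-invariant.

Expression phenotypes (for eQTN scans) are masked per transcript at 5.0
MADs from the *non-zero* median, zeros being treated as unobserved; a
transcript is kept when non-outlier observed values cover more than 20% of
the population.

Association p-values are controlled with BH step-up at \(q = 0.1\)
(`bh_fdr()`, backed by `p.adjust`). The two-round hierarchical procedure
for transcript phenotypes applies BH at \(q_1 = 0.1\) across phenotypes to
a per-phenotype summary p-value, then the Gavrilov–Benjamini–Sarkar
adaptive step-down within surviving phenotypes at \(q_2 = 5.1\times10^{-4}\),
with critical values

\[
c_i = \frac{i\,q_2}{m + 1 - i\,(1 - q_2)} .
\]

The round-1 summary statistic is not uniquely determined by the procedure's
usual description; this package defaults to each phenotype's minimum
p-value (the natural screening statistic in the hierarchical-testing
literature) and exposes `summary_fn` so another reduction can be chosen.
Note that the GBS step-down is *adaptive*: beyond rank \(1/(1-q)\) its
critical values exceed BH's, so it can legitimately reject more than BH on
signal-dense inputs — the tests assert its prefix coherence and
step-down/step-up ordering rather than a false "subset of BH" relation.

## Validation procedures

**Shuffled-data correlation comparison.** Each row of the expression (or
methylation) matrix is independently permuted across samples, preserving
every gene's value multiset while destroying sample-linked structure. From
each of `n_shuffles` shuffled matrices, `n_subsample` Spearman correlations
are drawn from uniformly sampled distinct gene pairs (without replacement,
so exhaustible small cases reproduce the full correlation multiset
exactly); a matching observed pool is drawn and the two pools are compared
with a two-sided Wilcoxon rank-sum test (exact enumeration when the smaller
pool has \(\le 8\) values and no ties). The supra-threshold fractions
(\(|\rho| \ge\) the layer cut) of both pools are reported alongside.

**GO-functional intersect score.** A functional network connects every pair
of genes sharing a GO term, weighted \(1/c\) for a term annotated to \(c\)
genes — any positive proportionality constant cancels in the
observed-vs-null comparison, so the simplest inverse size is used. Terms on
more than 1000 genes are dropped (generic functions would swamp the
network), and a pair sharing several terms keeps only its best edge (ties
broken by term id). The intersect score of a gene network is the sum of GO
edge weights over gene pairs present in both, each pair counted once
regardless of how many layers contribute it; anchor–anchor pairs count by
default (a flag excludes them). The observed merged LOE network is compared
against `n_random = 100` randomized network sets: each replicate holds
anchors and edge structure fixed and relabels the distinct 1-hop neighbors
of every layer with distinct genes drawn uniformly from the genome minus
the anchor set (a bijection — with-replacement draws would merge nodes and
change the network size), then the full scoring/thresholding/merging is
re-run on the relabeled layers. The summary reports the empirical
exceedance p-value with the add-one permutation convention,
\(p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(n+1)\).
The randomization loop runs through a lean vectorized replica of the
scoring path, pinned against the reference implementation in the test
suite.

**GO enrichment** of candidate sets uses the upper-tail hypergeometric test
with BH correction at 0.1 across tested terms; terms with zero overlap are
skipped. Annotations are taken as a flat gene-to-term table — no DAG
ancestor propagation.

## The synthetic world generator

`simulate_world()` builds a complete desk-scale study: ~1,000 genes on 10
chromosomes, 20 anchor genes, 8 anchor metabolites, 64 expression and 10
methylation samples (that asymmetry is what motivates the comethylation
discount), 100 genotyped samples, and 15 planted candidates whose per-layer
anchor partner counts are chosen to populate all three tiers and include
three designed failures (breadth two, or breadth three without any GWAS
edge). The ground truth implied by the design — depths, breadth, discounted
depth, high-LOE membership, tier — is emitted alongside the data and is
what the end-to-end tests compare against.

Design choices worth knowing:

* **Correlation blocks.** Expression blocks share a latent factor with
  loading \(\sqrt{0.97}\), far above the 0.85 cut so recovery at 64 samples
  is effectively deterministic. Methylation blocks are exact monotone
  copies of their latent (Spearman exactly 1): with only 10 samples a noisy
  0.97 target would clear the 0.95 cut too unreliably for exact-recovery
  assertions. An optional matrix-wide factor (`global_rho`) emulates the
  tissue-driven global covariance of real expression atlases and is used in
  the shuffle-validation scenarios.
* **The clean configuration.** After drawing, the generator verifies the
  realized Spearman matrix and redraws background features involved in any
  spurious supra-threshold pair (a real risk for the 10-sample methylation
  layer, where chance \(|\rho| \ge 0.95\) occurs at roughly \(10^{-4}\) per
  pair over ~\(5\times10^5\) pairs). The same verify-and-redraw guard
  applies to genotypes. Planted margins, not test outcomes, define these
  rules: the generator guarantees that the only supra-threshold structure
  is the planted structure.
* **Genotypes.** Planted co-segregating pairs copy an exactly balanced
  homozygous pattern (half dosage 0, half dosage 2) with a 2% per-sample
  flip probability, placed in genes > 10 kb apart or on different
  chromosomes; a decoy pair with CCC = 1 sits ~7 kb apart to exercise the
  distance rule; background SNPs are binomial with MAF 0.15–0.4.
* **TPM-like values.** Matrices are lognormal monotone transforms of the
  latent Gaussians *without* per-sample renormalization to \(10^6\):
  per-sample scaling would reshuffle within-gene ranks and break the
  planted Spearman structure. `tpm_from_counts()` performs true TPM
  normalization for real count data.
* **What is not emulated:** kinship and coalescent LD, metabolite
  covariance structure, count noise (the matrices are continuous),
  GO DAG structure, and genome-scale dimensions. Passing tests demonstrate
  correctness of the algorithms under controlled signal, not statistical
  power on real populations.

## Numerical and representation choices

Edges are undirected and stored once under canonical node ordering
(`node_a < node_b`), rows sorted by (layer, node_a, node_b), so writers are
byte-deterministic and independent of edge insertion order. Metabolite
nodes carry a `met:` namespace on ingest, making gene/metabolite collisions
impossible in the shared node space. Spearman uses average ranks for ties;
zero-variance features are excluded from correlation layers (undefined
\(\rho\)) with a message. Gene coordinates are 1-based inclusive; BED input
is converted on read. Pair subsampling unranks uniform pair indices into
the upper triangle with a floating-point-corrected inverse, so pools are
drawn without replacement in \(O(n)\) memory. Every stochastic routine
takes a seed, and the pipeline derives per-stage seeds by stable hashing of
stage names so stages are independently reproducible.

Problem sizes used by the test-suite and the acceptance script — 50 random
multilayer oracle instances up to 500 genes x 6 layers, the default
1,000-gene world, shuffle validation at 10 shuffles x 10,000 subsamples on
a 150-gene block matrix, and 50 replicate GO-validation worlds of 200 genes
with 100 randomized network sets each — are the package's reference
desk-scale conditions; all scale up through the corresponding parameters.

## Limitations

The package consumes association tables (GWAS and rare-variant region
p-values) rather than fitting mixed models or kernel tests itself; VCF
support covers the GT-only dialect; multi-hop neighborhood expansion beyond
explicit network unions is out of scope, as is automated literature mining
for the exclusion list. The CCC transcription follows the allele-table
formulation described above; users wanting a different SNP–SNP measure
should use the pluggable `pair_fn`.
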