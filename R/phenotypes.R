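# Phenotype cleaning and multiple-testing procedures applied before
# association edges enter the LOE pipeline.

#' MAD outlier filter for a phenotype vector
#'
#' Masks samples lying more than `k` median absolute deviations from the
#' population median. The MAD is unscaled (`median(|x - median(x)|)`, no
#' 1.4826 consistency constant): deviations are counted directly in MADs.
#'
#' @param x Numeric phenotype vector (missing values stay unmasked but are
#'   ignored when computing the median and MAD).
#' @param k Number of MADs beyond which a sample is an outlier (default 6).
#' @return Logical vector, `TRUE` for retained samples. If the MAD is zero
#'   the threshold is undefined: nothing is masked and a warning is emitted.
#' @export
#' @examples
#' mad_outlier_filter(c(1, 2, 3, 4, 100))   # last sample masked
mad_outlier_filter <- function(x, k = 6) {
  if (sum(!is.na(x)) < 3) abort("need at least 3 non-missing values")
  med <- stats::median(x, na.rm = TRUE)
  madv <- mad_unscaled(x)
  if (madv == 0) {
    warn("MAD is zero; outlier threshold undefined, no samples masked")
    return(rep(TRUE, length(x)))
  }
  keep <- abs(x - med) <= k * madv
  keep[is.na(keep)] <- TRUE
  keep
}

#' Mask outlying expression phenotypes and select retained transcripts
#'
#' Per transcript (row), values deviating from the median of the *non-zero*
#' values by more than `mad_threshold` unscaled MADs (of the non-zero values)
#' are masked to `NA`; zeros are treated as unobserved, not as outliers. A
#' transcript is retained when its non-outlier observed (non-zero) values
#' cover more than `retain_frac` of the samples. All-zero transcripts are
#' dropped and counted in a message.
#'
#' @param tpm Transcript x sample TPM matrix.
#' @param mad_threshold MAD multiple for masking (default 5).
#' @param retain_frac Minimum fraction of the population with a non-outlier
#'   observed value (default 0.2).
#' @return List with `masked` (matrix restricted to retained transcripts,
#'   outliers set `NA`) and `retained` (transcript ids).
#' @export
mask_expression_phenotypes <- function(tpm, mad_threshold = 5.0, retain_frac = 0.2) {
  assert_matrix(tpm, "tpm")
  n <- ncol(tpm)
  masked <- tpm
  observed <- tpm != 0
  all_zero <- rowSums(observed) == 0
  ok_frac <- logical(nrow(tpm))
  for (i in which(!all_zero)) {
    v <- tpm[i, ]
    nz <- v[v != 0]
    med <- stats::median(nz)
    madv <- stats::median(abs(nz - med))
    out <- if (madv > 0) abs(v - med) > mad_threshold * madv else rep(FALSE, n)
    masked[i, out] <- NA
    ok_frac[i] <- sum(v != 0 & !out) > retain_frac * n
  }
  if (any(all_zero)) {
    inform(sprintf("dropped %d all-zero transcript(s)", sum(all_zero)))
  }
  retained <- rownames(tpm)[ok_frac & !all_zero]
  list(masked = masked[retained, , drop = FALSE], retained = retained)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Standard BH step-up: with sorted p-values \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, reject \eqn{H_{(i)}} for all \eqn{i \le k^* = \max\{i : p_{(i)}
#' \le i q / m\}}.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param q FDR level (default 0.1).
#' @return Tibble of class `multiple_testing` with `p_value`, `q_value`
#'   (BH-adjusted), `rejected`, in the input order; attributes `procedure`
#'   and `level`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.1)
bh_fdr <- function(p, q = 0.1) {
  if (length(p) == 0) {
    return(structure(tibble(p_value = double(), q_value = double(),
                            rejected = logical()),
                     procedure = "BH", level = q,
                     class = c("multiple_testing", class(tibble()))))
  }
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  qv <- stats::p.adjust(p, method = "BH")
  structure(tibble(p_value = p, q_value = qv, rejected = qv <= q),
            procedure = "BH", level = q,
            class = c("multiple_testing", class(tibble())))
}

#' Gavrilov-Benjamini-Sarkar adaptive step-down procedure
#'
#' Step-down with critical values \eqn{c_i = i q / (m + 1 - i (1 - q))}:
#' reject the `k` smallest hypotheses where `k` is the largest index such
#' that every sorted p-value up to `k` sits below its critical value.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param q FDR level (must be < 1).
#' @return Tibble of class `multiple_testing` with `p_value`, `rejected`,
#'   `critical` in the input order.
#' @export
gbs_stepdown <- function(p, q = 5.1e-4) {
  if (q >= 1) abort("q must be < 1")
  if (length(p) == 0) {
    return(structure(tibble(p_value = double(), critical = double(),
                            rejected = logical()),
                     procedure = "GBS_stepdown", level = q,
                     class = c("multiple_testing", class(tibble()))))
  }
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  m <- length(p)
  ord <- order(p)
  crit <- seq_len(m) * q / (m + 1 - seq_len(m) * (1 - q))
  below <- p[ord] <= crit
  k <- if (below[1]) max(which(cumsum(!below) == 0)) else 0L
  rejected <- logical(m)
  if (k > 0) rejected[ord[seq_len(k)]] <- TRUE
  critical <- numeric(m)
  critical[ord] <- crit
  structure(tibble(p_value = p, critical = critical, rejected = rejected),
            procedure = "GBS_stepdown", level = q,
            class = c("multiple_testing", class(tibble())))
}

#' Two-round hierarchical multiple-testing correction
#'
#' Round 1 applies BH at `q1` across phenotypes to a per-phenotype summary
#' p-value (by default each phenotype's minimum p-value); round 2 applies the
#' Gavrilov-Benjamini-Sarkar step-down at `q2` within each surviving
#' phenotype. An association is significant iff it passes both rounds.
#'
#' @param p_by_phenotype Named list of numeric p-value vectors, one per
#'   phenotype.
#' @param q1 Round-1 BH level (default 0.1).
#' @param q2 Round-2 GBS level (default 5.1e-4).
#' @param summary_fn Function reducing a phenotype's p-values to the round-1
#'   summary statistic (default `min`).
#' @return Tibble with `phenotype`, `p_value`, `round1_pass`, `significant`.
#' @export
hierarchical_correction <- function(p_by_phenotype, q1 = 0.1, q2 = 5.1e-4,
                                    summary_fn = min) {
  if (q2 >= 1) abort("q2 must be < 1")
  stopifnot(is.list(p_by_phenotype), !is.null(names(p_by_phenotype)))
  summaries <- vapply(p_by_phenotype, summary_fn, numeric(1))
  r1 <- bh_fdr(unname(summaries), q = q1)
  pass1 <- setNames(r1$rejected, names(p_by_phenotype))
  imap(p_by_phenotype, function(p, ph) {
    sig <- if (pass1[[ph]] && length(p) > 0) gbs_stepdown(p, q = q2)$rejected
           else rep(FALSE, length(p))
    tibble(phenotype = ph, p_value = p, round1_pass = pass1[[ph]],
           significant = sig)
  }) |> list_rbind()
}

#' Filter SNPs on minor allele frequency and missingness
#'
#' MAF is recomputed from the dosages over non-missing samples
#' (`min(af, 1 - af)` with `af` the alt-allele frequency).
#'
#' @param g A `genotype_matrix`.
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @param max_missing Maximum tolerated per-SNP missingness fraction
#'   (default 1, i.e. no missingness filter).
#' @return A filtered `genotype_matrix`; the `meta` tibble gains `maf` and
#'   `missing_frac` columns.
#' @export
maf_filter <- function(g, min_maf = 0.01, max_missing = 1) {
  dos <- g$dosages
  n_ok <- rowSums(!is.na(dos))
  af <- rowSums(dos, na.rm = TRUE) / (2 * pmax(n_ok, 1))
  maf <- pmin(af, 1 - af)
  miss <- 1 - n_ok / ncol(dos)
  keep <- maf >= min_maf & miss <= max_missing & n_ok > 0
  meta <- g$meta
  meta$maf <- unname(maf)
  meta$missing_frac <- unname(miss)
  genotype_matrix(dos[keep, , drop = FALSE], meta[keep, , drop = FALSE])
}
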