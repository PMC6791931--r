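# Internal helpers shared across modules.

#' Namespace metabolite identifiers
#'
#' Metabolite node ids are prefixed with `"met:"` on ingest so a metabolite can
#' never collide with a gene id in a shared node namespace.
#'
#' @param ids Character vector of metabolite identifiers.
#' @return Character vector with the `met:` prefix applied (idempotent).
#' @export
#' @examples
#' met_id(c("sucrose", "met:syringin"))
met_id <- function(ids) {
  ifelse(startsWith(ids, "met:"), ids, paste0("met:", ids))
}

#' Node kind from a namespaced identifier
#'
#' @param ids Character vector of node ids.
#' @return `"metabolite"` for `met:`-prefixed ids, `"gene"` otherwise.
#' @export
node_kind <- function(ids) {
  ifelse(startsWith(ids, "met:"), "metabolite", "gene")
}

# Unscaled median absolute deviation: median(|x - median(x)|).
# The pipeline counts "MADs from the median" directly, so no consistency
# constant is applied.
mad_unscaled <- function(x) {
  x <- x[!is.na(x)]
  stats::median(abs(x - stats::median(x)))
}

# Derive a reproducible stage seed from a global seed and a stage name.
# Stable across sessions (pure arithmetic on UTF-8 code points), kept
# below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1e9
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Evaluate `expr` under a temporary RNG seed (no-op if seed is NULL).
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate %s id(s): %s", what,
                  paste(utils::head(dup, 5), collapse = ", ")))
  }
  invisible(ids)
}

assert_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) abort(sprintf("%s must be a numeric matrix", what))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("%s must carry feature rownames and sample colnames", what))
  }
  assert_unique(rownames(m), "feature")
  assert_unique(colnames(m), "sample")
  invisible(m)
}
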