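# broom-style tidiers for the pipeline's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an LOE score table into long per-layer depths
#'
#' @param x An `loe_scores` table.
#' @param ... Unused.
#' @return Tibble `gene`, `layer`, `depth`.
#' @export
tidy.loe_scores <- function(x, ...) {
  depth_cols <- grep("^depth_", names(x), value = TRUE)
  depth_cols <- setdiff(depth_cols, c("depth_total", "depth_minus_cometh"))
  as_tibble(x)[c("gene", depth_cols)] |>
    pivot_longer(dplyr::all_of(depth_cols), names_to = "layer",
                 values_to = "depth", names_prefix = "depth_")
}

#' One-row summary of an LOE score table
#'
#' @param x An `loe_scores` table.
#' @param ... Unused.
#' @return Tibble with gene counts by breadth and totals.
#' @export
glance.loe_scores <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_connected = sum(x$breadth > 0),
         n_breadth_ge_3 = sum(x$breadth >= 3),
         n_breadth_ge_4 = sum(x$breadth >= 4),
         max_depth_total = if (nrow(x)) max(x$depth_total) else 0L)
}

#' Tidy a null-distribution validation
#'
#' @param x An `loe_null` object.
#' @param ... Unused.
#' @return Tibble of randomized intersect scores (`replicate`, `score`).
#' @export
tidy.loe_null <- function(x, ...) {
  tibble(replicate = seq_along(x$null), score = x$null)
}

#' One-row summary of a null-distribution validation
#'
#' @param x An `loe_null` object.
#' @param ... Unused.
#' @return Tibble with observed score, null range/mean and empirical p.
#' @export
glance.loe_null <- function(x, ...) {
  tibble(observed = x$observed, n_random = x$n, null_min = x$null_min,
         null_max = x$null_max, null_mean = x$null_mean, p_value = x$p_value)
}

#' Tidy a shuffle validation into its correlation pools
#'
#' @param x An `loe_shuffle_validation` object.
#' @param ... Unused.
#' @return Tibble `pool` (observed/shuffled), `rho`.
#' @export
tidy.loe_shuffle_validation <- function(x, ...) {
  bind_rows(tibble(pool = "observed", rho = x$observed),
            tibble(pool = "shuffled", rho = x$shuffled))
}

#' One-row summary of a shuffle validation
#'
#' @param x An `loe_shuffle_validation` object.
#' @param ... Unused.
#' @return Tibble with the rank-sum statistic and p-value and the
#'   supra-threshold fractions of each pool.
#' @export
glance.loe_shuffle_validation <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         threshold = x$threshold, frac_observed = x$frac_observed,
         frac_shuffled = x$frac_shuffled,
         n_shuffles = x$n_shuffles, n_subsample = x$n_subsample)
}

#' @export
print.loe_shuffle_validation <- function(x, ...) {
  cat(sprintf(paste0("Shuffle validation: rank-sum p = %.3g; ",
                     "|rho| >= %.2f in %.3g%% observed vs %.3g%% shuffled\n"),
              x$p_value, x$threshold, 100 * x$frac_observed,
              100 * x$frac_shuffled))
  invisible(x)
}
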