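# ggplot2 diagnostics for the pipeline's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Breadth-score distribution of an LOE score table
#'
#' The breadth histogram is the diagnostic used to choose the merge
#' threshold (look for the inflection point in the tail).
#'
#' @param object An `loe_scores` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loe_scores <- function(object, ...) {
  df <- filter(as_tibble(object), .data$breadth > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$breadth)) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "LOE breadth score", y = "genes (log scale)",
                  title = "Distribution of LOE breadth scores") +
    ggplot2::theme_minimal()
}

#' Null-distribution histogram with the observed statistic
#'
#' @param object An `loe_null` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loe_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60", colour = "grey20") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "intersect score (randomized networks)", y = "count",
                  title = sprintf("Observed %.4f vs %d randomized networks (p = %.3g)",
                                  object$observed, object$n, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Observed vs shuffled correlation distributions
#'
#' @param object An `loe_shuffle_validation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loe_shuffle_validation <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$rho, fill = .data$pool)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "Spearman correlation", y = "count", fill = NULL,
                  title = sprintf("Observed vs shuffled correlations (rank-sum p = %.3g)",
                                  object$p_value)) +
    ggplot2::theme_minimal()
}
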