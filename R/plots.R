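#' Scree-style plot of a PCA screen
#'
#' Contribution rate per component with the screening threshold drawn as
#' a horizontal line; components above the line feed the gene scores.
#'
#' @param object An `opca_pca` object.
#' @param n_components Number of leading components to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.opca_pca <- function(object, n_components = 30, ...) {
  k <- min(n_components, length(object$contribution_rates))
  df <- tibble::tibble(component = seq_len(k),
                       contribution = object$contribution_rates[seq_len(k)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$contribution)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = object$contribution_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "principal component", y = "contribution rate",
                  title = "PCA contribution rates",
                  subtitle = sprintf("dashed line: %.3g screening threshold",
                                     object$contribution_threshold)) +
    ggplot2::theme_minimal()
}

#' Dependency trace of a greedy reduct
#'
#' Cumulative dependency degree after each accepted gene, showing how
#' much of the sample set the growing panel classifies consistently.
#'
#' @param object An `opca_reduct` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.opca_reduct <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$cumulative_dependency)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = df$rank, labels = df$gene_id) +
    ggplot2::labs(x = NULL, y = "dependency degree",
                  title = sprintf("Greedy reduct at delta = %g", object$delta_used)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Radius-sweep summary of a fitted pipeline
#'
#' Cross-validated score and panel size across the delta grid, with the
#' chosen radius marked.
#'
#' @param object An `opca_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.opca_fit <- function(object, ...) {
  df <- object$search
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$score)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_vline(xintercept = object$reduct$delta_used,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "neighborhood radius", y = "cross-validated accuracy",
                  title = "Radius sweep",
                  subtitle = sprintf("chosen delta = %g, %d genes selected",
                                     object$reduct$delta_used,
                                     length(object$reduct$selected))) +
    ggplot2::theme_minimal()
}

#' Bar chart comparing feature selectors
#'
#' Companion plot for [compare_selectors()]: selected-panel size,
#' precision and accuracy per method.
#'
#' @param comparison Tibble returned by [compare_selectors()].
#' @return A ggplot.
#' @export
plot_comparison <- function(comparison) {
  long <- tidyr::pivot_longer(comparison,
                              cols = c("n_genes", "precision", "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Selector comparison") +
    ggplot2::theme_minimal()
}
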