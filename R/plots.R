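#' Plot the pooled micro-averaged ROC curve of a cross-validation report
#'
#' @param object A `field_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.field_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Micro-averaged ROC (pooled AUC = %.2f, mean fold AUC = %.2f)",
                      object$micro_auc, object$mean_fold_auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the ARI model-selection curve over module counts
#'
#' @param object A `field_modsel` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.field_modsel <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k, y = .data$ari)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$k_star, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Number of gene modules (k)",
                  y = "ARI vs proximity annotation",
                  title = sprintf("Module-count selection (k* = %d)",
                                  object$k_star)) +
    ggplot2::theme_minimal()
}

#' Plot PCA scores coloured by proximity to tumour
#'
#' @param object A `field_pca` object.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.field_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$site)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      title = sprintf("PCA of the top %d most variable genes", object$n_genes),
      colour = "Site"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of the sample-by-module matrix reordered by biclusters
#'
#' Rows (samples) and columns (modules) are sorted by their bicluster label,
#' making the joint partitions contiguous so concordant biclusters appear as
#' blocks along the diagonal.
#'
#' @param bicluster A `field_bicluster` object.
#' @return A ggplot tile map.
#' @export
plot_bicluster_heatmap <- function(bicluster) {
  stopifnot(inherits(bicluster, "field_bicluster"))
  m <- bicluster$matrix
  row_ord <- order(bicluster$row_labels, names(bicluster$row_labels))
  col_ord <- order(bicluster$col_labels, names(bicluster$col_labels))
  df <- tibble::as_tibble(m[row_ord, col_ord, drop = FALSE],
                          rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "module",
                        values_to = "score") |>
    dplyr::mutate(
      sample_id = factor(.data$sample_id, levels = rownames(m)[row_ord]),
      module = factor(.data$module, levels = colnames(m)[col_ord])
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$sample_id,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B") +
    ggplot2::labs(x = "Gene module", y = "Sample",
                  fill = "Mean z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}
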