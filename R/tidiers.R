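#' Tidy a cross-validation report
#'
#' @param x A `field_cv` object from [lopo_cv()].
#' @param ... Unused.
#' @return A tibble with one row per fold: `fold`, `patient_id`, `auc`,
#'   `n_test`, `n_selected`.
#' @export
#' @exportS3Method generics::tidy
tidy.field_cv <- function(x, ...) {
  x$folds |>
    dplyr::mutate(n_selected = purrr::map_int(.data$selected, length)) |>
    dplyr::select("fold", "patient_id", "auc", "n_test", "n_selected")
}

#' @rdname tidy.field_cv
#' @return For `glance()`: a one-row tibble `micro_auc`, `mean_fold_auc`,
#'   `n_folds`.
#' @export
#' @exportS3Method generics::glance
glance.field_cv <- function(x, ...) {
  tibble::tibble(micro_auc = x$micro_auc, mean_fold_auc = x$mean_fold_auc,
                 n_folds = x$n_folds)
}

#' Tidy a biclustering
#'
#' @param x A `field_bicluster` object.
#' @param ... Unused.
#' @return A tibble `item`, `axis` (`"sample"`/`"module"`), `bicluster`.
#' @export
#' @exportS3Method generics::tidy
tidy.field_bicluster <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(item = names(x$row_labels), axis = "sample",
                   bicluster = unname(x$row_labels)),
    tibble::tibble(item = names(x$col_labels), axis = "module",
                   bicluster = unname(x$col_labels))
  )
}

#' Tidy a module-count selection curve
#'
#' @param x A `field_modsel` object from [choose_module_count()].
#' @param ... Unused.
#' @return The per-k ARI curve as a tibble `k`, `ari`.
#' @export
#' @exportS3Method generics::tidy
tidy.field_modsel <- function(x, ...) x$curve

#' @rdname tidy.field_modsel
#' @return For `glance()`: a one-row tibble `k_star`, `ari_at_k_star`,
#'   `n_biclusters`.
#' @export
#' @exportS3Method generics::glance
glance.field_modsel <- function(x, ...) {
  tibble::tibble(
    k_star = x$k_star,
    ari_at_k_star = x$curve$ari[x$curve$k == x$k_star],
    n_biclusters = x$n_biclusters
  )
}

#' Tidy a mutation-enrichment result
#'
#' @param x A `field_enrichment` object.
#' @param ... Unused.
#' @return A one-row tibble with the 2x2 counts, the Yates chi-square
#'   statistic and p-value, and the odds ratio with its Woolf interval.
#' @export
#' @exportS3Method generics::tidy
tidy.field_enrichment <- function(x, ...) {
  tibble::tibble(
    a = x$table[1, 1], b = x$table[1, 2],
    c = x$table[2, 1], d = x$table[2, 2],
    chi2 = x$chi2, p_value = x$p_value, odds_ratio = x$odds_ratio,
    ci_low = x$ci_low, ci_high = x$ci_high
  )
}

#' Tidy a proximity PCA
#'
#' @param x A `field_pca` object from [pca_proximity()].
#' @param ... Unused.
#' @return The per-sample score tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.field_pca <- function(x, ...) x$scores

#' @rdname tidy.field_pca
#' @return For `glance()`: a tibble `pc`, `variance`, `proportion`.
#' @export
#' @exportS3Method generics::glance
glance.field_pca <- function(x, ...) x$variance
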