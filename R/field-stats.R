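#' Two-sided p-value for a Pearson correlation coefficient
#'
#' Uses the exact t-transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param r Pearson correlation in \[-1, 1\] (vectorised).
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p-value(s).
#' @export
pearson_p <- function(r, n) {
  if (any(abs(r) > 1)) abort("|r| must be <= 1")
  if (n < 3) abort("n must be >= 3")
  t_stat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 0))
  ifelse(abs(r) == 1, 0, 2 * pt(t_stat, df = n - 2, lower.tail = FALSE))
}

#' Uncapped Bonferroni adjustment
#'
#' Multiplies each p-value by the number of tests without capping at 1, so
#' adjusted values above 1 are reported as-is (significance is still read
#' as adjusted p < threshold).
#'
#' @param p Raw p-value(s) in \[0, 1\].
#' @param m Number of tests (>= 1).
#' @return `p * m`, uncapped.
#' @export
bonferroni <- function(p, m) {
  if (any(p < 0 | p > 1)) abort("p must lie in [0, 1]")
  if (any(m < 1)) abort("m must be >= 1")
  p * m
}

#' Correlate module scores with proximity to tumour
#'
#' For each module, computes the Pearson correlation between its per-sample
#' summary score and the ordinal proximity rank (O1 = 0, D1 = 1, D2 = 2,
#' T = 3), the two-sided p-value from the t-transform, and the uncapped
#' Bonferroni adjustment over the number of modules tested. Zero-variance
#' module scores get an undefined r and p = 1 with a warning.
#'
#' @param summary_matrix Samples-by-modules matrix
#'   (see [module_summary_matrix()]).
#' @param annotation Sample annotation tibble supplying `proximity_rank`
#'   for each row of the matrix.
#' @param alpha Significance threshold applied to the adjusted p-value.
#' @return A tibble `module`, `pearson_r`, `p_value`, `p_bonferroni`,
#'   `significant`, `n_samples`, `m_tests`, sorted by module.
#' @export
correlate_modules <- function(summary_matrix, annotation, alpha = 0.05) {
  check_matrix(summary_matrix, "summary matrix")
  ann <- annotation[match(rownames(summary_matrix), annotation$sample_id), ]
  if (anyNA(ann$proximity_rank)) {
    abort("proximity_rank undefined for some samples")
  }
  n <- nrow(summary_matrix)
  if (n < 3) abort("at least 3 samples required")
  m <- ncol(summary_matrix)
  ranks <- ann$proximity_rank
  out <- purrr::map_dfr(seq_len(m), function(j) {
    score <- summary_matrix[, j]
    if (sd(score) == 0) {
      warn(paste0("module ", colnames(summary_matrix)[j],
                  " has zero-variance scores; p set to 1"))
      r <- NA_real_
      p <- 1
    } else {
      r <- cor(score, ranks)
      p <- pearson_p(r, n)
    }
    tibble::tibble(module = colnames(summary_matrix)[j], pearson_r = r,
                   p_value = p)
  })
  out |>
    dplyr::mutate(
      p_bonferroni = bonferroni(.data$p_value, m),
      significant = .data$p_bonferroni < alpha,
      n_samples = n, m_tests = m
    )
}

#' Mutation enrichment of module genes over background genes
#'
#' Tests whether module genes are more often mutated in breast-cancer
#' cohorts than background genes, via a 2x2 contingency table, Yates
#' continuity-corrected chi-square test, the odds ratio `ad / bc`, and its
#' Woolf 95 percent confidence interval
#' `exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. The analysis is
#' restricted to genes present in the catalogue (i.e. assayed in at least
#' one cohort). The default counting unit is the (gene, cohort) pair, pooled
#' across cohorts; `pooling = "gene"` collapses to one per-gene indicator
#' (mutated in any cohort).
#'
#' @param module_genes Character vector of module gene ids.
#' @param background_genes Character vector of background gene ids
#'   (disjoint from `module_genes`).
#' @param catalog Mutation catalogue tibble (`cohort_id`, `gene_id`,
#'   `mutated`), e.g. from [read_mutations()] or [simulate_cohort()].
#' @param pooling `"gene_cohort"` (default) or `"gene"`.
#' @param conf_level Confidence level of the Woolf interval.
#' @return An object of class `field_enrichment`: `table` (2x2 counts a-d),
#'   `chi2`, `p_value`, `odds_ratio`, `ci_low`, `ci_high`, `pooling`.
#' @export
mutation_enrichment <- function(module_genes, background_genes, catalog,
                                pooling = c("gene_cohort", "gene"),
                                conf_level = 0.95) {
  pooling <- match.arg(pooling)
  if (length(intersect(module_genes, background_genes)) > 0) {
    abort("module and background gene sets must be disjoint")
  }
  cat_tbl <- tibble::as_tibble(catalog)
  if (pooling == "gene") {
    cat_tbl <- cat_tbl |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(mutated = any(.data$mutated), .groups = "drop")
  }
  in_mod <- cat_tbl$gene_id %in% module_genes
  in_bg <- cat_tbl$gene_id %in% background_genes
  if (!any(in_mod) || !any(in_bg)) {
    abort("module or background does not intersect the mutation catalogue")
  }
  a <- sum(in_mod & cat_tbl$mutated)
  b <- sum(in_mod & !cat_tbl$mutated)
  cc <- sum(in_bg & cat_tbl$mutated)
  d <- sum(in_bg & !cat_tbl$mutated)
  if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) {
    abort("contingency table has a zero margin")
  }
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("module", "background"),
                                c("mutated", "not_mutated")))
  test <- suppressWarnings(chisq.test(tab, correct = TRUE))
  cells <- c(a, b, cc, d)
  if (any(cells == 0)) {
    warn("zero cell in contingency table; Haldane 0.5 correction applied")
    cells <- cells + 0.5
  }
  or <- cells[1] * cells[4] / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  structure(
    list(table = tab, chi2 = unname(test$statistic),
         p_value = unname(test$p.value), odds_ratio = or,
         ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
         conf_level = conf_level, pooling = pooling),
    class = "field_enrichment"
  )
}

#' @export
print.field_enrichment <- function(x, ...) {
  cat("Mutation enrichment (", x$pooling, " units)\n", sep = "")
  print(x$table)
  cat(sprintf("  Yates chi2 = %.3f, p = %.3g\n", x$chi2, x$p_value))
  cat(sprintf("  OR = %.3f, %g%% CI (%.3f, %.3f)\n", x$odds_ratio,
              100 * x$conf_level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Pathway over-representation analysis of a gene module
#'
#' Upper-tail hypergeometric test of the overlap between the module and each
#' gene set, against a fixed gene universe, with Benjamini-Hochberg q-values
#' across sets. Sets with no member in the universe are skipped with a
#' warning. The expected overlap `set_size * module_size / universe_size`
#' is reported alongside.
#'
#' @param module_genes Character vector of module gene ids (subset of
#'   `universe`).
#' @param gene_sets Named list of character vectors (e.g.
#'   [read_gene_sets()]).
#' @param universe Character vector of all assayable gene ids.
#' @return A tibble `gene_set`, `overlap`, `set_size`, `module_size`,
#'   `universe_size`, `expected`, `p_value`, `q_value`, sorted by p.
#' @export
ora <- function(module_genes, gene_sets, universe) {
  universe <- unique(universe)
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% universe)) {
    abort("module genes must be a subset of the universe")
  }
  n_u <- length(universe)
  n_m <- length(module_genes)
  rows <- purrr::imap_dfr(gene_sets, function(set, name) {
    set_u <- intersect(unique(set), universe)
    if (length(set_u) == 0) {
      warn(paste0("gene set ", name, " has no member in the universe; skipped"))
      return(tibble::tibble())
    }
    k <- length(intersect(set_u, module_genes))
    tibble::tibble(
      gene_set = name, overlap = k, set_size = length(set_u),
      module_size = n_m, universe_size = n_u,
      expected = length(set_u) * n_m / n_u,
      p_value = phyper(k - 1, length(set_u), n_u - length(set_u), n_m,
                       lower.tail = FALSE)
    )
  })
  if (nrow(rows) == 0) abort("no gene set overlaps the universe")
  rows |>
    dplyr::mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    dplyr::arrange(.data$p_value, .data$gene_set)
}
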