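#' Residualize duct and tumour expression on the matched contralateral sample
#'
#' For every QC-passing non-contralateral sample (sites D1, D2, T) an
#' ordinary least-squares regression across genes is fitted with the same
#' patient's contralateral (O1) profile as predictor:
#' `x(g, s) = a + b * x(g, O1_p) + r(g, s)`. The residuals retain the part of
#' expression not attributable to the patient's baseline — the proximity
#' signal plus noise. Patients without a QC-passing O1 sample are skipped
#' with a warning.
#'
#' @param expr Genes-by-samples log2 expression matrix.
#' @param annotation Sample annotation tibble (see [sample_annotation()]).
#' @param baseline_site Site label of the contralateral baseline (`"O1"`).
#' @return A list of class `field_residuals`: `residuals` (genes x duct/tumour
#'   samples matrix) and `fits` (tibble `sample_id`, `patient_id`, `site`,
#'   `proximity_rank`, `intercept`, `slope`, `r_squared`).
#' @export
residualize_on_contralateral <- function(expr, annotation,
                                         baseline_site = "O1") {
  check_matrix(expr, "expression matrix")
  ann <- annotation[annotation$qc_flag == "pass" &
                      annotation$sample_id %in% colnames(expr), ]
  base <- ann[ann$site == baseline_site, ]
  targets <- ann[ann$site != baseline_site, ]
  no_base <- setdiff(unique(targets$patient_id), base$patient_id)
  if (length(no_base) > 0) {
    warn(paste0("no QC-passing ", baseline_site, " sample for patient(s) ",
                paste(no_base, collapse = ", "), "; their samples skipped"))
    targets <- targets[!targets$patient_id %in% no_base, ]
  }
  if (nrow(targets) == 0) abort("no samples left to residualize")
  res <- matrix(NA_real_, nrow(expr), nrow(targets),
                dimnames = list(rownames(expr), targets$sample_id))
  fits <- purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    s <- targets$sample_id[i]
    o1 <- base$sample_id[match(targets$patient_id[i], base$patient_id)]
    y <- expr[, s]
    x <- expr[, o1]
    fit <- stats::lm.fit(cbind(1, x), y)
    res[, i] <<- fit$residuals
    tibble::tibble(
      sample_id = s, patient_id = targets$patient_id[i],
      site = targets$site[i], proximity_rank = targets$proximity_rank[i],
      intercept = unname(fit$coefficients[1]),
      slope = unname(fit$coefficients[2]),
      r_squared = 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    )
  })
  structure(list(residuals = res, fits = fits), class = "field_residuals")
}

#' Per-sample variance in residual expression explained by copy number
#'
#' For each residualized sample, regresses the residual expression vector on
#' the same sample's gene-level copy-number log-ratios (OLS with intercept,
#' across the gene intersection) and reports the coefficient of
#' determination. Residuals and copy number come from the same epithelial
#' sample, i.e. the same distance from the tumour.
#'
#' @param residuals A `field_residuals` object (or genes x samples matrix).
#' @param cna Gene-level copy-number log-ratio matrix.
#' @return A tibble `sample_id`, `r_squared`, `slope`, `intercept`, `n_genes`.
#' @export
cna_variance_explained <- function(residuals, cna) {
  res <- if (inherits(residuals, "field_residuals")) {
    residuals$residuals
  } else {
    residuals
  }
  check_matrix(res, "residual matrix")
  check_matrix(cna, "CNA matrix")
  genes <- intersect(rownames(res), rownames(cna))
  if (length(genes) < 10) {
    abort("fewer than 10 genes shared between residuals and CNA")
  }
  samples <- intersect(colnames(res), colnames(cna))
  if (length(samples) == 0) abort("no shared samples between residuals and CNA")
  purrr::map_dfr(samples, function(s) {
    y <- res[genes, s]
    x <- cna[genes, s]
    if (var(x) == 0) {
      warn(paste0("zero-variance CNA vector for sample ", s,
                  "; R-squared reported as 0"))
      return(tibble::tibble(sample_id = s, r_squared = 0, slope = NA_real_,
                            intercept = mean(y), n_genes = length(genes)))
    }
    fit <- stats::lm.fit(cbind(1, x), y)
    tibble::tibble(
      sample_id = s,
      r_squared = 1 - sum(fit$residuals^2) / sum((y - mean(y))^2),
      slope = unname(fit$coefficients[2]),
      intercept = unname(fit$coefficients[1]),
      n_genes = length(genes)
    )
  })
}

#' Principal components of the most variable genes, versus tumour proximity
#'
#' Ranks genes by sample variance, keeps the top fraction (ties broken by
#' gene id), centres per gene, and computes principal components over
#' samples. Each component's sign is fixed so its largest-magnitude gene
#' loading is positive.
#'
#' @param expr Genes-by-samples matrix (>= 3 samples).
#' @param annotation Sample annotation tibble.
#' @param top_fraction Fraction of genes to keep, in (0, 1].
#' @return A list of class `field_pca`: `scores` (tibble with `sample_id`,
#'   `site`, `proximity_rank`, `PC1`, `PC2`, ...), `loadings` (genes x PCs
#'   matrix), `variance` (tibble `pc`, `variance`, `proportion`).
#' @export
pca_proximity <- function(expr, annotation, top_fraction = 0.10) {
  check_matrix(expr, "expression matrix")
  if (ncol(expr) < 3) abort("at least 3 samples required for PCA")
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    abort("top_fraction must lie in (0, 1]")
  }
  v <- apply(expr, 1, var)
  keep_n <- ceiling(top_fraction * nrow(expr))
  ord <- order(-v, rownames(expr))
  x <- expr[ord[seq_len(keep_n)], , drop = FALSE]
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  # deterministic orientation: largest-|loading| gene positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ann <- annotation[match(colnames(expr), annotation$sample_id), ]
  scores <- dplyr::bind_cols(
    ann[, c("sample_id", "site", "proximity_rank")],
    tibble::as_tibble(pc$x)
  )
  pc_var <- pc$sdev^2
  variance <- tibble::tibble(
    pc = seq_along(pc_var),
    variance = pc_var,
    proportion = pc_var / sum(pc_var)
  )
  structure(list(scores = scores, loadings = pc$rotation,
                 variance = variance, n_genes = keep_n),
            class = "field_pca")
}
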