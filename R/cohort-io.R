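#' Build a validated sample annotation table
#'
#' A cohort annotation maps each sample to its patient and its sampling site
#' along the duct, and carries the ordinal proximity rank used throughout the
#' pipeline (O1 = 0 contralateral duct, D1 = 1, D2 = 2 along the involved
#' duct, T = 3 tumour).
#'
#' @param df Data frame with columns `sample_id`, `patient_id`, `site`, and
#'   optionally `histology` and `qc_flag`.
#' @param sites Named integer vector mapping site labels to proximity ranks;
#'   defaults to the four-site design `c(O1 = 0, D1 = 1, D2 = 2, T = 3)`.
#' @return A tibble with columns `sample_id`, `patient_id`, `site`,
#'   `proximity_rank`, `histology`, `qc_flag`.
#' @export
sample_annotation <- function(df, sites = default_sites()) {
  need <- c("sample_id", "patient_id", "site")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("sample sheet lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.null(names(sites)) || anyNA(names(sites))) {
    abort("`sites` must be a named vector of proximity ranks")
  }
  if (is.unsorted(sites, strictly = TRUE)) {
    abort("site proximity ranks must be strictly increasing in site order")
  }
  ann <- tibble::as_tibble(df)
  bad_site <- setdiff(unique(ann$site), names(sites))
  if (length(bad_site) > 0) {
    abort(paste0("unknown site label(s): ", paste(bad_site, collapse = ", ")))
  }
  if (anyDuplicated(ann$sample_id)) {
    abort("duplicate sample_id in sample sheet")
  }
  dup <- duplicated(ann[, c("patient_id", "site")])
  if (any(dup)) {
    abort(paste0("duplicate (patient_id, site) pair(s): ",
                 paste(unique(paste0(ann$patient_id[dup], "/", ann$site[dup])),
                       collapse = ", ")))
  }
  ann$proximity_rank <- as.integer(sites[as.character(ann$site)])
  if (!"histology" %in% names(ann)) ann$histology <- NA_character_
  if (!"qc_flag" %in% names(ann)) ann$qc_flag <- "pass"
  ann[, c("sample_id", "patient_id", "site", "proximity_rank",
          "histology", "qc_flag")]
}

#' Read a sample sheet
#'
#' @param path TSV file with columns `sample_id`, `patient_id`, `site` and
#'   optionally `histology`.
#' @inheritParams sample_annotation
#' @return A validated annotation tibble (see [sample_annotation()]).
#' @export
read_sample_sheet <- function(path, sites = default_sites()) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  sample_annotation(df, sites = sites)
}

read_numeric_tsv <- function(path, what) {
  header <- strsplit(readr::read_lines(path, n_max = 1L), "\t", fixed = TRUE)[[1]]
  ids <- header[-1]
  if (anyDuplicated(ids)) {
    abort(paste0(what, " file ", path, ": duplicate sample column(s) ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "),
                 " (line 1)"))
  }
  df <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_double(),
                            readr::col_character()),
    progress = FALSE, name_repair = "minimal"
  ))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0(what, " file ", path, ": parse error at line ",
                 probs$row[1], " (", probs$expected[1], ")"))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    abort(paste0(what, " file ", path, ": missing or non-numeric value at line ",
                 bad + 1L))
  }
  m
}

#' Read a gene-level expression matrix
#'
#' Reads a genes-by-samples TSV (first column `gene_id` or probe id, header
#' row of sample ids, log2 abundance values). When a probe annotation is
#' supplied, probes without a gene symbol are dropped and the remainder are
#' collapsed to gene level by [collapse_probes()]. Rows are ordered
#' lexicographically by gene id; columns follow the sample sheet when given,
#' otherwise file order.
#'
#' @param path TSV path.
#' @param probe_annotation Optional data frame with columns `probe_id`,
#'   `gene_id`; probes absent from it (or mapped to `NA`) are dropped.
#' @param annotation Optional sample annotation tibble used to order (and
#'   restrict to) its QC-passing samples.
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path, probe_annotation = NULL, annotation = NULL) {
  m <- read_numeric_tsv(path, "expression")
  if (!is.null(probe_annotation)) {
    map <- tibble::as_tibble(probe_annotation)
    map <- map[!is.na(map$gene_id), c("probe_id", "gene_id")]
    keep <- intersect(rownames(m), map$probe_id)
    if (length(keep) == 0) abort("no probe maps to a gene symbol")
    m <- collapse_probes(m[keep, , drop = FALSE], map)
  }
  m <- m[order(rownames(m)), , drop = FALSE]
  if (!is.null(annotation)) {
    keep <- annotation$sample_id[annotation$qc_flag == "pass"]
    missing <- setdiff(keep, colnames(m))
    if (length(missing) > 0) {
      abort(paste0("sample(s) in annotation absent from matrix: ",
                   paste(missing, collapse = ", ")))
    }
    m <- m[, keep, drop = FALSE]
  }
  m
}

#' Read a gene-level copy-number log-ratio matrix
#'
#' Same format and conventions as [read_expression()].
#' @inheritParams read_expression
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
read_cna <- function(path, annotation = NULL) {
  read_expression(path, probe_annotation = NULL, annotation = annotation)
}

#' Write a genes-by-samples matrix as TSV
#'
#' @param m Numeric matrix with gene ids as row names and sample ids as
#'   column names.
#' @param path Output TSV path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Collapse probe-level rows to gene level by averaging
#'
#' Multiple probes mapping to the same gene symbol are averaged per sample
#' (arithmetic mean, no variance or expression filtering); single-probe genes
#' pass through unchanged.
#'
#' @param probe_matrix Numeric matrix, probes in rows.
#' @param probe_to_gene Data frame with columns `probe_id`, `gene_id`; every
#'   probe in `probe_matrix` must map to exactly one gene.
#' @return A numeric matrix with unique gene ids as row names, rows in
#'   lexicographic gene order.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene) {
  check_matrix(probe_matrix, "probe matrix")
  map <- tibble::as_tibble(probe_to_gene)[, c("probe_id", "gene_id")]
  multi <- unique(map$probe_id[duplicated(map[, "probe_id"])])
  multi <- intersect(multi, rownames(probe_matrix))
  if (length(multi) > 0) {
    abort(paste0("probe(s) mapped to multiple genes: ",
                 paste(head(multi, 5), collapse = ", ")))
  }
  idx <- match(rownames(probe_matrix), map$probe_id)
  if (anyNA(idx)) {
    abort(paste0("probe(s) without a gene mapping: ",
                 paste(head(rownames(probe_matrix)[is.na(idx)], 5),
                       collapse = ", ")))
  }
  gene <- map$gene_id[idx]
  sums <- rowsum(probe_matrix, group = gene)
  counts <- as.vector(table(gene)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

#' Flag outlier samples with a sum-of-standardized-error boxplot rule
#'
#' For each sample the statistic is the sum over genes of its squared
#' deviation from the gene mean, standardized by the gene variance
#' (plus a small guard `delta`):
#' \deqn{E(s) = \sum_g (x_{gs} - \bar x_g)^2 / (s_g^2 + \delta).}
#' Samples whose statistic exceeds the upper Tukey fence
#' (Q3 + `fence` * IQR of the per-sample statistics) are flagged as outliers.
#'
#' @param expr Genes-by-samples matrix (at least 4 samples).
#' @param annotation Optional annotation tibble; when given, the returned
#'   tibble carries its columns with `qc_flag` updated.
#' @param standardize Divide squared deviations by the gene variance
#'   (default); `FALSE` uses raw squared error.
#' @param fence IQR multiplier for the upper fence (Tukey's 1.5 by default).
#' @param delta Variance guard for (near-)constant genes.
#' @return A tibble with `sample_id`, `qc_score`, `qc_flag`
#'   (`"pass"`/`"outlier"`), joined to `annotation` when provided.
#' @export
flag_outliers <- function(expr, annotation = NULL, standardize = TRUE,
                          fence = 1.5, delta = 1e-8) {
  check_matrix(expr, "expression matrix")
  if (ncol(expr) < 4) {
    abort("at least 4 samples are required for boxplot fences")
  }
  mu <- rowMeans(expr)
  dev2 <- (expr - mu)^2
  e <- if (standardize) {
    v <- apply(expr, 1, var)
    colSums(dev2 / (v + delta))
  } else {
    colSums(dev2)
  }
  q <- quantile(e, c(0.25, 0.75), names = FALSE)
  upper <- q[2] + fence * (q[2] - q[1])
  out <- tibble::tibble(
    sample_id = colnames(expr),
    qc_score = unname(e),
    qc_flag = unname(ifelse(e > upper, "outlier", "pass"))
  )
  if (!is.null(annotation)) {
    ann <- annotation[, setdiff(names(annotation), c("qc_flag", "qc_score"))]
    out <- dplyr::left_join(ann, out, by = "sample_id")
  }
  out
}

#' Read a MAF-like mutation table into a per-cohort catalogue
#'
#' The input lists one row per (cohort, gene, sample, variant class); the
#' catalogue collapses this to one row per (cohort, gene) with a boolean
#' `mutated` (mutated in at least one sample of that cohort) and the number
#' of mutated samples.
#'
#' @param path TSV with columns `cohort_id`, `gene_id`, `sample_id`,
#'   `variant_class`.
#' @return A tibble `cohort_id`, `gene_id`, `mutated`, `n_mutated_samples`.
#' @export
read_mutations <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("cohort_id", "gene_id", "sample_id")
  if (!all(need %in% names(df))) {
    abort("mutation table needs columns cohort_id, gene_id, sample_id")
  }
  df |>
    dplyr::distinct(.data$cohort_id, .data$gene_id, .data$sample_id) |>
    dplyr::count(.data$cohort_id, .data$gene_id, name = "n_mutated_samples") |>
    dplyr::mutate(mutated = .data$n_mutated_samples > 0L) |>
    dplyr::select("cohort_id", "gene_id", "mutated", "n_mutated_samples") |>
    dplyr::arrange(.data$cohort_id, .data$gene_id)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (one set per line: name, description, genes).
#' @return A named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  fgsea::gmtPathways(path)
}
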