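#' Agglomerate genes into modules by Ward clustering
#'
#' Bottom-up Ward agglomeration (Euclidean distance between gene expression
#' profiles across samples, `ward.D2` criterion so merges minimise the
#' within-cluster variance increase) cut at `k` modules. Modules are numbered
#' 0..k-1 in order of their first member gene (gene-id order), making the
#' labelling deterministic.
#'
#' @param expr Genes-by-samples matrix of the (selected) genes to cluster.
#' @param k Number of modules (1 <= k <= number of genes).
#' @return A tibble `gene_id`, `module`, of class `field_modules`, with the
#'   `hclust` tree stored in attribute `"tree"`.
#' @export
agglomerate_genes <- function(expr, k) {
  check_matrix(expr, "expression matrix")
  if (k < 1) abort("k must be >= 1")
  if (k > nrow(expr)) abort("k exceeds the number of genes")
  ord <- order(rownames(expr))
  x <- expr[ord, , drop = FALSE]
  tree <- hclust(dist(x, method = "euclidean"), method = "ward.D2")
  raw <- cutree(tree, k = k)
  # renumber clusters 0..k-1 by first gene occurrence
  first_seen <- unique(raw)
  module <- match(raw, first_seen) - 1L
  out <- tibble::tibble(gene_id = rownames(x), module = module) |>
    dplyr::arrange(.data$gene_id)
  attr(out, "tree") <- tree
  class(out) <- c("field_modules", class(out))
  out
}

#' Sample-by-module summary matrix of mean z-scored expression
#'
#' Each gene is z-scored across samples (constant genes contribute z = 0),
#' then averaged within its module: entry (s, m) is the mean z-score of
#' module-m genes in sample s.
#'
#' @param expr Genes-by-samples matrix covering every gene of `assignment`.
#' @param assignment Tibble `gene_id`, `module` (e.g. [agglomerate_genes()]).
#' @return A samples-by-modules numeric matrix; columns named by module
#'   index.
#' @export
module_summary_matrix <- function(expr, assignment) {
  check_matrix(expr, "expression matrix")
  missing <- setdiff(assignment$gene_id, rownames(expr))
  if (length(missing) > 0) {
    abort(paste0("assignment covers gene(s) absent from the matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  x <- expr[assignment$gene_id, , drop = FALSE]
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  modules <- sort(unique(assignment$module))
  out <- vapply(modules, function(m) {
    colMeans(z[assignment$module == m, , drop = FALSE])
  }, numeric(ncol(x)))
  matrix(out, nrow = ncol(x),
         dimnames = list(colnames(x), as.character(modules)))
}

#' Bipartite spectral co-clustering of a samples-by-modules matrix
#'
#' Treats the (shifted-nonnegative) matrix as a bipartite graph between
#' samples and modules and partitions both sides jointly: the matrix is
#' normalized as `An = Dr^(-1/2) A Dc^(-1/2)`, the `ceil(log2 n_biclusters)`
#' singular vector pairs after the first are kept, rows are embedded as
#' `Dr^(-1/2) U` and columns as `Dc^(-1/2) V`, and the stacked embedding is
#' k-means clustered (10 restarts). Rows and columns inherit the joint
#' cluster labels, so each sample and each module belongs to exactly one
#' bicluster.
#'
#' @param m Samples-by-modules numeric matrix (any sign; it is shifted by its
#'   global minimum before normalization).
#' @param n_biclusters Number of biclusters (<= min(dim)).
#' @param seed Seed for the k-means restarts.
#' @param max_tries Re-seeding attempts when a bicluster ends up empty on one
#'   axis.
#' @return An object of class `field_bicluster`: `row_labels` (named, one per
#'   sample), `col_labels` (named, one per module), `n_biclusters`, `matrix`.
#' @export
spectral_cocluster <- function(m, n_biclusters = 4, seed = 1L,
                               max_tries = 10L) {
  check_matrix(m, "summary matrix")
  if (n_biclusters < 2) abort("n_biclusters must be >= 2")
  if (n_biclusters > min(dim(m))) {
    abort("n_biclusters exceeds min(rows, cols)")
  }
  a <- m - min(m)
  if (any(rowSums(a) == 0) || any(colSums(a) == 0)) {
    abort("all-zero row or column after nonnegativity shift")
  }
  dr <- 1 / sqrt(rowSums(a))
  dc <- 1 / sqrt(colSums(a))
  an <- a * outer(dr, dc)
  ell <- ceiling(log2(n_biclusters))
  if (min(dim(m)) < ell + 1) {
    abort("matrix too small for the requested number of biclusters")
  }
  sv <- svd(an, nu = ell + 1, nv = ell + 1)
  u <- dr * sv$u[, 2:(ell + 1), drop = FALSE]
  v <- dc * sv$v[, 2:(ell + 1), drop = FALSE]
  emb <- rbind(u, v)
  n_rows <- nrow(m)
  for (try in seq_len(max_tries)) {
    km <- try(with_seed(derive_seed(seed, try - 1L),
                        kmeans(emb, centers = n_biclusters, nstart = 10)),
              silent = TRUE)
    if (inherits(km, "try-error")) next
    lab <- km$cluster
    row_labels <- lab[seq_len(n_rows)]
    col_labels <- lab[-seq_len(n_rows)]
    if (length(unique(row_labels)) == n_biclusters &&
        length(unique(col_labels)) == n_biclusters) {
      names(row_labels) <- rownames(m)
      names(col_labels) <- colnames(m)
      return(structure(
        list(row_labels = row_labels, col_labels = col_labels,
             n_biclusters = n_biclusters, matrix = m),
        class = "field_bicluster"
      ))
    }
  }
  abort(paste0("could not find ", n_biclusters,
               " biclusters populated on both axes in ", max_tries,
               " attempts"))
}

#' @export
print.field_bicluster <- function(x, ...) {
  cat("Bipartite spectral co-clustering:", x$n_biclusters, "biclusters\n")
  cat("  samples per bicluster:",
      paste(table(x$row_labels), collapse = " "), "\n")
  cat("  modules per bicluster:",
      paste(table(x$col_labels), collapse = " "), "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same elements:
#' 0 is the expectation under random assignment, 1 indicates identical
#' partitions up to relabeling.
#'
#' @param part_a,part_b Label vectors over the same elements (length >= 2).
#' @return An object of class `field_ari`: `value` and the `contingency`
#'   table of the two partitions.
#' @export
adjusted_rand <- function(part_a, part_b) {
  if (length(part_a) != length(part_b)) {
    abort("partitions must cover the same elements")
  }
  n <- length(part_a)
  if (n < 2) abort("at least 2 elements required")
  tab <- table(part_a, part_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  value <- if (max_index == expected) 1 else {
    (sum_ij - expected) / (max_index - expected)
  }
  structure(list(value = value, contingency = tab), class = "field_ari")
}

#' @export
print.field_ari <- function(x, ...) {
  cat("Adjusted Rand index:", format(x$value, digits = 4), "\n")
  invisible(x)
}

#' Choose the module count that best matches the proximity annotation
#'
#' For each candidate k, agglomerates the genes into k modules, summarizes,
#' co-clusters samples and modules, and scores the sample partition against
#' the proximity annotation with the adjusted Rand index. The selected k is
#' the argmax of the curve (smallest k on ties). Grid points that are
#' infeasible for the requested bicluster count, or where co-clustering
#' fails, are recorded with `NA`.
#'
#' @param expr Genes-by-samples matrix of selected genes.
#' @param annotation Sample annotation tibble.
#' @param k_grid Candidate module counts (default 2:40).
#' @param n_biclusters Number of biclusters passed to
#'   [spectral_cocluster()]; defaults to the number of site classes.
#' @param seed Seed for co-clustering.
#' @return An object of class `field_modsel`: `curve` (tibble `k`, `ari`),
#'   `k_star`, `best` (the `field_modules` assignment at `k_star`).
#' @export
choose_module_count <- function(expr, annotation, k_grid = 2:40,
                                n_biclusters = 4, seed = 1L) {
  check_matrix(expr, "expression matrix")
  ann <- annotation[match(colnames(expr), annotation$sample_id), ]
  k_grid <- k_grid[k_grid <= nrow(expr)]
  if (length(k_grid) == 0) abort("empty k grid after bounds check")
  ari <- purrr::map_dbl(k_grid, function(k) {
    tryCatch({
      assign <- agglomerate_genes(expr, k)
      summ <- module_summary_matrix(expr, assign)
      bc <- spectral_cocluster(summ, n_biclusters = n_biclusters,
                               seed = derive_seed(seed, k))
      adjusted_rand(bc$row_labels, ann$site)$value
    }, error = function(e) NA_real_)
  })
  if (all(is.na(ari))) abort("co-clustering failed at every grid point")
  k_star <- k_grid[which.max(ari)]  # which.max skips NA, smallest k on ties
  structure(
    list(curve = tibble::tibble(k = k_grid, ari = ari), k_star = k_star,
         best = agglomerate_genes(expr, k_star),
         n_biclusters = n_biclusters),
    class = "field_modsel"
  )
}

#' @export
print.field_modsel <- function(x, ...) {
  cat("Module-count selection over k =", min(x$curve$k), "..",
      max(x$curve$k), "\n")
  cat("  k* =", x$k_star, "with sample-vs-proximity ARI =",
      format(max(x$curve$ari, na.rm = TRUE), digits = 3), "\n")
  invisible(x)
}
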