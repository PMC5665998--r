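#' Rank genes by mutual information with the site label
#'
#' Uses the nearest-neighbour mutual-information estimator for a continuous
#' variable against a discrete label: for each sample, the distance to its
#' `k`-th nearest neighbour within the same class defines a radius, and the
#' estimate combines digamma terms over the class counts and the number of
#' neighbours (across all classes) inside that radius. Negative estimates are
#' clipped to zero. A seeded, vanishingly small jitter breaks ties between
#' identical expression values; constant genes score 0.
#'
#' @param expr Genes-by-samples matrix.
#' @param labels Character/factor vector of site labels, one per column.
#' @param k_neighbors Neighbour count `k` (must be below the smallest class
#'   size).
#' @param fraction Fraction of genes to flag as selected (top of the
#'   ranking); `ceiling(fraction * n_genes)` genes are selected.
#' @param seed Seed for the tie-breaking jitter.
#' @return A tibble `gene_id`, `mi`, `rank`, `selected`, ordered by rank.
#' @export
mi_rank <- function(expr, labels, k_neighbors = 3, fraction = 0.30, seed = 1L) {
  check_matrix(expr, "expression matrix")
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(expr))
  counts <- table(labels)
  if (length(counts) < 2) abort("at least 2 classes required")
  if (k_neighbors >= min(counts)) {
    abort("k_neighbors must be smaller than the smallest class size")
  }
  mi <- with_seed(seed, {
    apply(expr, 1, function(x) mi_mixed_knn(x, labels, k_neighbors))
  })
  n_sel <- ceiling(fraction * nrow(expr))
  out <- tibble::tibble(gene_id = rownames(expr), mi = unname(mi)) |>
    dplyr::arrange(dplyr::desc(.data$mi), .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  selected = .data$rank <= n_sel)
  out
}

# kNN mutual information between continuous x and discrete y (nats).
mi_mixed_knn <- function(x, y, k) {
  n <- length(x)
  if (sd(x) == 0) return(0)
  x <- x + runif(n, -1, 1) * 1e-10 * sd(x)
  d <- abs(outer(x, x, "-"))
  diag(d) <- Inf
  radius <- numeric(n)
  kvec <- integer(n)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    kk <- min(k, length(idx) - 1L)
    sub <- d[idx, idx, drop = FALSE]
    radius[idx] <- apply(sub, 1, function(r) sort(r, partial = kk)[kk])
    kvec[idx] <- kk
  }
  m <- rowSums(d <= radius)
  n_y <- as.vector(table(y)[y])
  est <- digamma(n) + mean(digamma(kvec) - digamma(n_y) - digamma(m))
  max(est, 0)
}

#' Train one-vs-rest linear max-margin scorers
#'
#' Fits, per site class, a soft-margin linear support-vector scorer (hinge
#' loss, penalty `C`) of that class against the rest, on per-gene z-scored
#' features (training statistics). Classes absent from the training data get
#' no scorer and are ranked lowest at prediction time.
#'
#' @param x Samples-by-features numeric matrix (rows = samples).
#' @param labels Class label per row.
#' @param C Soft-margin penalty (default 1).
#' @param classes Class order for the score columns (default the four sites
#'   O1, D1, D2, T intersected with observed labels, then any extras).
#' @return An object of class `field_ovr` with a [predict()] method returning
#'   a samples-by-classes decision-score matrix.
#' @export
train_ovr_linear <- function(x, labels, C = 1.0, classes = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) abort("training set must contain >= 2 classes")
  if (is.null(classes)) {
    canon <- names(default_sites())
    classes <- c(intersect(canon, unique(labels)),
                 setdiff(sort(unique(labels)), canon))
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale_, "/")
  scorers <- lapply(classes, function(cls) {
    if (!cls %in% labels) return(NULL)
    y <- factor(ifelse(labels == cls, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(x = xs, y = y, kernel = "linear", cost = C, scale = FALSE,
               fitted = FALSE)
  })
  names(scorers) <- classes
  structure(list(scorers = scorers, classes = classes,
                 center = center, scale = scale_, C = C),
            class = "field_ovr")
}

#' @export
#' @rdname train_ovr_linear
#' @param object A `field_ovr` model.
#' @param newdata Samples-by-features matrix to score.
#' @param ... Unused.
predict.field_ovr <- function(object, newdata, ...) {
  xs <- sweep(sweep(newdata, 2, object$center, "-"), 2, object$scale, "/")
  scores <- vapply(object$classes, function(cls) {
    sc <- object$scorers[[cls]]
    if (is.null(sc)) {
      rep(-.Machine$double.xmax, nrow(xs))
    } else {
      pr <- predict(sc, xs, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # orient so larger score = more like `cls`
      if (colnames(dv)[1] == "pos/neg") as.vector(dv) else -as.vector(dv)
    }
  }, numeric(nrow(xs)))
  matrix(scores, nrow = nrow(xs), dimnames = list(rownames(newdata),
                                                  object$classes))
}

#' Micro-averaged ROC curve and AUC
#'
#' Flattens the one-hot label indicator matrix and the matching decision
#' score matrix into a single binary problem over all N x K elements and
#' computes the ROC step curve and its area. The AUC equals the Mann-Whitney
#' statistic of scores at indicator-1 elements versus indicator-0 elements;
#' tied scores receive half credit (trapezoidal interpolation).
#'
#' @param indicator 0/1 matrix, one 1 per row (samples x classes).
#' @param scores Numeric matrix of the same shape.
#' @return A list of class `field_roc`: `roc` (tibble `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
micro_average_roc <- function(indicator, scores) {
  stopifnot(all(dim(indicator) == dim(scores)))
  lab <- as.vector(indicator)
  sc <- as.vector(scores)
  if (!all(lab %in% c(0, 1))) abort("indicator matrix must be 0/1")
  n1 <- sum(lab == 1)
  n0 <- sum(lab == 0)
  if (n1 == 0 || n0 == 0) {
    abort("flattened indicator is all-0 or all-1; AUC undefined")
  }
  r <- rank(sc)
  auc <- (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(sc, decreasing = TRUE)
  lab_o <- lab[ord]
  sc_o <- sc[ord]
  last_of_tie <- c(sc_o[-length(sc_o)] != sc_o[-1], TRUE)
  roc <- tibble::tibble(
    threshold = c(Inf, sc_o[last_of_tie]),
    tpr = c(0, cumsum(lab_o)[last_of_tie] / n1),
    fpr = c(0, cumsum(1 - lab_o)[last_of_tie] / n0)
  )
  structure(list(roc = roc, auc = auc), class = "field_roc")
}

#' One-hot indicator matrix for site labels
#'
#' @param labels Site label per sample.
#' @param classes Column order (default O1, D1, D2, T).
#' @return 0/1 matrix, samples x classes.
#' @export
label_indicator <- function(labels, classes = names(default_sites())) {
  out <- vapply(classes, function(cls) as.numeric(labels == cls),
                numeric(length(labels)))
  matrix(out, nrow = length(labels), dimnames = list(NULL, classes))
}

#' Leave-one-patient-out cross-validated proximity classification
#'
#' For each fold one patient's full site set is held out; mutual-information
#' gene selection and feature standardization are computed on the training
#' patients (when `select_within_fold`, the default — set it to `FALSE` to
#' select once globally), a one-vs-rest linear max-margin model is trained,
#' and the held-out samples are scored. Reports per-fold and pooled
#' micro-averaged ROC/AUC.
#'
#' @param expr Genes-by-samples matrix.
#' @param annotation Sample annotation tibble; only QC-passing samples that
#'   appear in `expr` are used.
#' @param fraction Fraction of genes kept by MI selection.
#' @param C Soft-margin penalty.
#' @param k_neighbors MI estimator neighbour count.
#' @param select_within_fold Recompute the gene selection inside each
#'   training fold (honest default) or once on all samples.
#' @param folds `"lopo"` (default) or an integer number of patient-grouped
#'   folds.
#' @param seed Seed driving the MI jitter and fold shuffling.
#' @return An object of class `field_cv`: `folds` (tibble `patient_id`
#'   or `fold`, `auc`, `n_test`, `selected` list-column), `indicator` and
#'   `scores` matrices over all held-out samples, `roc` (pooled tibble),
#'   `micro_auc` (pooled), `mean_fold_auc`.
#' @export
lopo_cv <- function(expr, annotation, fraction = 0.30, C = 1.0,
                    k_neighbors = 3, select_within_fold = TRUE,
                    folds = "lopo", seed = 1L) {
  check_matrix(expr, "expression matrix")
  ann <- annotation[annotation$qc_flag == "pass" &
                      annotation$sample_id %in% colnames(expr), ]
  if (length(unique(ann$patient_id)) < 3) {
    abort("at least 3 patients required for cross-validation")
  }
  classes <- names(default_sites())
  classes <- c(intersect(classes, unique(ann$site)),
               setdiff(sort(unique(ann$site)), classes))
  patients <- sort(unique(ann$patient_id))
  fold_of <- if (identical(folds, "lopo")) {
    stats::setNames(seq_along(patients), patients)
  } else {
    k <- as.integer(folds)
    perm <- with_seed(derive_seed(seed, 999L), sample(length(patients)))
    stats::setNames(rep_len(seq_len(k), length(patients))[order(perm)],
                    patients)
  }
  n_folds <- length(unique(fold_of))
  # the MI estimator needs k below the smallest per-class count in the
  # smallest training fold; clamp rather than fail on small cohorts
  min_train_class <- min(vapply(unique(fold_of), function(f) {
    tr <- ann[!ann$patient_id %in% patients[fold_of == f], ]
    min(table(tr$site))
  }, numeric(1)))
  k_neighbors <- max(1L, min(k_neighbors, as.integer(min_train_class) - 1L))
  global_sel <- NULL
  if (!select_within_fold) {
    global_sel <- mi_rank(expr[, ann$sample_id, drop = FALSE], ann$site,
                          k_neighbors = k_neighbors, fraction = fraction,
                          seed = derive_seed(seed, 0L))
  }
  fold_results <- purrr::map(sort(unique(fold_of)), function(f) {
    test_pat <- patients[fold_of == f]
    tr <- ann[!ann$patient_id %in% test_pat, ]
    te <- ann[ann$patient_id %in% test_pat, ]
    sel <- if (select_within_fold) {
      mi_rank(expr[, tr$sample_id, drop = FALSE], tr$site,
              k_neighbors = k_neighbors, fraction = fraction,
              seed = derive_seed(seed, f))
    } else {
      global_sel
    }
    genes <- sel$gene_id[sel$selected]
    model <- train_ovr_linear(t(expr[genes, tr$sample_id, drop = FALSE]),
                              tr$site, C = C, classes = classes)
    sc <- predict(model, t(expr[genes, te$sample_id, drop = FALSE]))
    ind <- label_indicator(te$site, classes)
    rownames(ind) <- te$sample_id
    fold_auc <- micro_average_roc(ind, sc)$auc
    list(fold = f, patients = test_pat, ind = ind, scores = sc,
         auc = fold_auc, selected = genes)
  })
  indicator <- do.call(rbind, purrr::map(fold_results, "ind"))
  scores <- do.call(rbind, purrr::map(fold_results, "scores"))
  pooled <- micro_average_roc(indicator, scores)
  folds_tbl <- tibble::tibble(
    fold = purrr::map_int(fold_results, "fold"),
    patient_id = purrr::map_chr(fold_results,
                                ~ paste(.x$patients, collapse = ",")),
    auc = purrr::map_dbl(fold_results, "auc"),
    n_test = purrr::map_int(fold_results, ~ nrow(.x$ind)),
    selected = purrr::map(fold_results, "selected")
  )
  structure(
    list(folds = folds_tbl, indicator = indicator, scores = scores,
         roc = pooled$roc, micro_auc = pooled$auc,
         mean_fold_auc = mean(folds_tbl$auc), classes = classes,
         n_folds = n_folds),
    class = "field_cv"
  )
}

#' @export
print.field_cv <- function(x, ...) {
  cat("Leave-one-patient-out proximity classification\n")
  cat("  folds:          ", x$n_folds, "\n")
  cat("  mean fold AUC:  ", sprintf("%.3f", x$mean_fold_auc), "\n")
  cat("  pooled microAUC:", sprintf("%.3f", x$micro_auc), "\n")
  invisible(x)
}
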