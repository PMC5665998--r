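test_that("cutting at the gene count yields singleton modules", {
  m <- rand_matrix(1, 12, 6)
  a <- agglomerate_genes(m, 12)
  expect_equal(sort(unique(a$module)), 0:11)
  expect_equal(nrow(a), 12)
  expect_error(agglomerate_genes(m, 0), "k must be")
})

test_that("well-separated planted gene blocks are recovered exactly", {
  co <- simulate_cohort(synthetic_config(
    n_genes = 100, n_modules = 2, module_size = 50,
    gradient_effect = c(5, -5), noise_sd = 0.3, patient_sd = 0.01,
    cna_coupling = 0, seed = 2
  ))
  a <- agglomerate_genes(co$expr, 2)
  truth <- co$truth$modules$module[match(a$gene_id,
                                         co$truth$modules$gene_id)]
  expect_equal(adjusted_rand(a$module, truth)$value, 1.0)
})

test_that("Ward partitions beat random partitions on within-cluster variance", {
  m <- rand_matrix(3, 40, 8)
  k <- 4
  a <- agglomerate_genes(m, k)
  wcv <- function(assignment) {
    sum(vapply(split(a$gene_id, assignment), function(genes) {
      x <- m[genes, , drop = FALSE]
      sum(sweep(x, 2, colMeans(x))^2)
    }, numeric(1)))
  }
  ward_obj <- wcv(a$module)
  set.seed(3)
  for (i in 1:100) {
    rand_part <- sample(rep_len(seq_len(k), 40))
    expect_lte(ward_obj, wcv(rand_part))
  }
})

test_that("module assignments sum to the gene count at every k", {
  m <- rand_matrix(4, 30, 6)
  for (k in c(2, 5, 11)) {
    a <- agglomerate_genes(m, k)
    expect_equal(length(unique(a$module)), k)
    expect_equal(sum(table(a$module)), 30)
  }
})

test_that("module summaries are mean z-scores with degenerate genes at zero", {
  m <- rand_matrix(5, 6, 5)
  m["G003", ] <- 7  # constant gene
  assign <- tibble::tibble(gene_id = rownames(m),
                           module = c(0L, 0L, 1L, 2L, 2L, 2L))
  summ <- module_summary_matrix(m, assign)
  z <- t(scale(t(m)))
  expect_equal(summ[, "0"], colMeans(z[c("G001", "G002"), ]))
  expect_equal(unname(summ[, "1"]), rep(0, 5))
  expect_equal(dim(summ), c(5, 3))
  # single-gene module equals that gene's z-scores
  single <- module_summary_matrix(m, tibble::tibble(gene_id = "G001",
                                                    module = 0L))
  expect_equal(single[, "0"], z["G001", ])
})

test_that("module summaries match a brute-force group-by oracle", {
  m <- rand_matrix(6, 50, 8)
  set.seed(6)
  assign <- tibble::tibble(gene_id = rownames(m),
                           module = sample(0:4, 50, replace = TRUE))
  summ <- module_summary_matrix(m, assign)
  z <- t(scale(t(m)))
  for (mod in 0:4) {
    genes <- assign$gene_id[assign$module == mod]
    expect_equal(summ[, as.character(mod)],
                 colMeans(z[genes, , drop = FALSE]), tolerance = 1e-12)
  }
})

test_that("an exact two-block matrix is co-clustered perfectly", {
  m <- rbind(cbind(matrix(5, 10, 3), matrix(0.1, 10, 2)),
             cbind(matrix(0.1, 8, 3), matrix(5, 8, 2)))
  dimnames(m) <- list(paste0("s", 1:18), paste0("m", 1:5))
  bc <- spectral_cocluster(m, 2, seed = 1)
  expect_equal(adjusted_rand(bc$row_labels, rep(1:2, c(10, 8)))$value, 1.0)
  expect_equal(adjusted_rand(bc$col_labels, rep(1:2, c(3, 2)))$value, 1.0)
})

test_that("co-clustering is equivariant to row and column permutations", {
  m <- rbind(cbind(matrix(4, 6, 3), matrix(0.2, 6, 3)),
             cbind(matrix(0.2, 6, 3), matrix(4, 6, 3)))
  dimnames(m) <- list(paste0("s", 1:12), paste0("m", 1:6))
  set.seed(7)
  ri <- sample(12)
  ci <- sample(6)
  bc1 <- spectral_cocluster(m, 2, seed = 5)
  bc2 <- spectral_cocluster(m[ri, ci], 2, seed = 5)
  expect_equal(adjusted_rand(bc1$row_labels,
                             bc2$row_labels[rownames(m)])$value, 1.0)
  expect_equal(adjusted_rand(bc1$col_labels,
                             bc2$col_labels[colnames(m)])$value, 1.0)
})

test_that("co-clustering is invariant to a constant shift of the matrix", {
  m <- rbind(cbind(matrix(3, 8, 2), matrix(0, 8, 2)),
             cbind(matrix(0, 8, 2), matrix(3, 8, 2)))
  dimnames(m) <- list(paste0("s", 1:16), paste0("m", 1:4))
  bc1 <- spectral_cocluster(m, 2, seed = 3)
  bc2 <- spectral_cocluster(m - 1.7, 2, seed = 3)
  expect_equal(adjusted_rand(bc1$row_labels, bc2$row_labels)$value, 1.0)
  expect_equal(adjusted_rand(bc1$col_labels, bc2$col_labels)$value, 1.0)
})

test_that("infeasible bicluster counts are rejected", {
  m <- rand_matrix(8, 6, 3)
  expect_error(spectral_cocluster(t(m), 4), "exceeds min")
})

test_that("gradient cohorts yield sample partitions aligned with proximity", {
  hits <- vapply(1:10, function(s) {
    co <- simulate_cohort(synthetic_config(n_genes = 400, module_size = 40,
                                           gradient_effect = 1.5,
                                           seed = 200 + s))
    sel <- mi_rank(co$expr, co$annotation$site, seed = s)
    es <- co$expr[sel$gene_id[sel$selected], , drop = FALSE]
    summ <- module_summary_matrix(es, agglomerate_genes(es, 20))
    bc <- tryCatch(spectral_cocluster(summ, 4, seed = s),
                   error = function(e) NULL)
    if (is.null(bc)) return(NA_real_)
    adjusted_rand(bc$row_labels, co$annotation$site)$value
  }, numeric(1))
  expect_gte(mean(hits > 0, na.rm = TRUE), 0.95)
})

test_that("identical partitions score ARI 1 and degenerate splits score 0", {
  expect_equal(adjusted_rand(rep(1:3, 4), rep(1:3, 4))$value, 1.0)
  expect_equal(adjusted_rand(rep("x", 10), as.character(1:10))$value, 0.0)
  expect_error(adjusted_rand(1, 1), "2 elements")
})

test_that("ARI matches the pair-counting oracle and an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(9)
  for (i in 1:50) {
    a <- sample(1:4, 12, replace = TRUE)
    b <- sample(1:3, 12, replace = TRUE)
    got <- adjusted_rand(a, b)$value
    expect_equal(got, ari_pair_oracle(a, b), tolerance = 1e-12)
    expect_equal(got, mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("ARI is symmetric and invariant to label permutation", {
  set.seed(10)
  a <- sample(1:3, 15, replace = TRUE)
  b <- sample(1:4, 15, replace = TRUE)
  expect_equal(adjusted_rand(a, b)$value, adjusted_rand(b, a)$value)
  relabeled <- c(9, 7, 8)[a]
  expect_equal(adjusted_rand(a, b)$value, adjusted_rand(relabeled, b)$value)
})

test_that("the module-count selection curve attains 1 on a planted block cohort", {
  bc <- make_block_cohort(11)
  ms <- choose_module_count(bc$expr, bc$annotation, k_grid = 4:10,
                            n_biclusters = 4, seed = 7)
  expect_equal(max(ms$curve$ari, na.rm = TRUE), 1.0)
  expect_equal(ms$curve$ari[ms$curve$k == ms$k_star], 1.0)
  # at the planted k the gene modules are recovered exactly
  a6 <- agglomerate_genes(bc$expr, 6)
  expect_equal(adjusted_rand(a6$module, bc$truth_module)$value, 1.0)
})

test_that("the selected k maximises the ARI curve and is reproducible", {
  bc <- make_block_cohort(12, n_modules = 4, module_size = 20)
  ms1 <- choose_module_count(bc$expr, bc$annotation, k_grid = 4:8,
                             n_biclusters = 4, seed = 5)
  ms2 <- choose_module_count(bc$expr, bc$annotation, k_grid = 4:8,
                             n_biclusters = 4, seed = 5)
  expect_identical(ms1$curve, ms2$curve)
  best <- max(ms1$curve$ari, na.rm = TRUE)
  expect_true(all(ms1$curve$ari <= best, na.rm = TRUE))
  expect_equal(ms1$curve$ari[ms1$curve$k == ms1$k_star], best)
  expect_s3_class(autoplot(ms1), "ggplot")
  expect_s3_class(plot_bicluster_heatmap(
    spectral_cocluster(module_summary_matrix(bc$expr, ms1$best),
                       4, seed = 5)), "ggplot")
})
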