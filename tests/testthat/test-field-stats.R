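test_that("correlation p-values agree with cor.test", {
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(12)
    y <- rnorm(12)
    r <- cor(x, y)
    expect_equal(pearson_p(r, 12), cor.test(x, y)$p.value, tolerance = 1e-12)
  }
  expect_equal(pearson_p(0, 30), 1.0)
  expect_equal(pearson_p(1, 10), 0.0)
})

test_that("correlation p-values agree with a permutation null", {
  set.seed(2)
  n <- 30
  x <- rnorm(n)
  y <- 0.3 * x + rnorm(n)
  r_obs <- cor(x, y)
  n_perm <- 4000
  r_null <- vapply(seq_len(n_perm), function(i) cor(x, sample(y)),
                   numeric(1))
  p_perm <- mean(abs(r_null) >= abs(r_obs))
  p_t <- pearson_p(r_obs, n)
  mc_se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(p_t - p_perm), 4 * mc_se + 0.005)
})

test_that("the Bonferroni adjustment is uncapped and monotone", {
  expect_equal(bonferroni(0.226, 20), 4.52, tolerance = 1e-2)
  expect_equal(bonferroni(0.0, 20), 0.0)
  expect_equal(bonferroni(pearson_p(0.101, 30), 20), 11.908,
               tolerance = 5e-4)
  p <- seq(0, 1, 0.1)
  expect_true(all(diff(bonferroni(p, 7)) >= 0))
  expect_true(all(bonferroni(0.3, 1:10) == 0.3 * (1:10)))
})

test_that("module-proximity correlation tables carry uncapped adjustments", {
  ann <- make_annotation(4)
  set.seed(3)
  m <- matrix(rnorm(16 * 3), 16, 3,
              dimnames = list(ann$sample_id, c("0", "1", "2")))
  m[, 1] <- ann$proximity_rank  # perfect positive correlation
  tab <- correlate_modules(m, ann)
  expect_equal(tab$pearson_r[1], 1.0, tolerance = 1e-10)
  expect_lt(tab$p_value[1], 1e-10)
  expect_true(tab$significant[1])
  expect_equal(tab$p_bonferroni, tab$p_value * 3)
  expect_equal(tab$n_samples, rep(16, 3))
  # zero-variance module scores degrade to p = 1 with a warning
  m[, 2] <- 0
  expect_warning(tab2 <- correlate_modules(m, ann), "zero-variance")
  expect_equal(tab2$p_value[2], 1)
  expect_false(tab2$significant[2])
})

test_that("a balanced contingency table shows no enrichment", {
  catalog <- tibble::tibble(
    cohort_id = "c1",
    gene_id = c(sprintf("m%d", 1:20), sprintf("b%d", 1:20)),
    mutated = rep(c(TRUE, FALSE, TRUE, FALSE), each = 10)
  )
  e <- mutation_enrichment(sprintf("m%d", 1:20), sprintf("b%d", 1:20),
                           catalog)
  expect_equal(e$odds_ratio, 1.0)
  expect_equal(e$chi2, 0.0)
  expect_equal(e$p_value, 1.0)
})

test_that("Yates chi-square, OR and Woolf CI match the formula oracle", {
  set.seed(4)
  for (i in 1:100) {
    cells <- sample(5:60, 4, replace = TRUE)
    mod <- sprintf("m%03d", seq_len(cells[1] + cells[2]))
    bg <- sprintf("b%03d", seq_len(cells[3] + cells[4]))
    catalog <- tibble::tibble(
      cohort_id = "c1", gene_id = c(mod, bg),
      mutated = c(rep(c(TRUE, FALSE), cells[1:2]),
                  rep(c(TRUE, FALSE), cells[3:4]))
    )
    e <- mutation_enrichment(mod, bg, catalog)
    o <- yates_oracle(cells[1], cells[2], cells[3], cells[4])
    expect_equal(e$chi2, o$chi2, tolerance = 1e-10)
    expect_equal(e$p_value, o$p, tolerance = 1e-10)
    expect_equal(e$odds_ratio, o$or, tolerance = 1e-10)
    expect_equal(c(e$ci_low, e$ci_high), o$ci, tolerance = 1e-10)
  }
})

test_that("the planted mutation odds ratio is covered by the Woolf interval", {
  covered <- vapply(1:25, function(s) {
    co <- simulate_cohort(synthetic_config(
      n_genes = 2200, module_size = 50, mutation_or = 1.5, seed = 300 + s
    ))
    mg <- co$truth$enriched_genes
    bg <- setdiff(rownames(co$expr), mg)
    e <- mutation_enrichment(mg, bg, co$mutations)
    e$ci_low <= 1.5 && 1.5 <= e$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})

test_that("enrichment statistics respect table symmetries", {
  catalog <- tibble::tibble(
    cohort_id = "c1",
    gene_id = c(sprintf("m%d", 1:50), sprintf("b%d", 1:80)),
    mutated = c(rep(c(TRUE, FALSE), c(20, 30)), rep(c(TRUE, FALSE), c(15, 65)))
  )
  e1 <- mutation_enrichment(sprintf("m%d", 1:50), sprintf("b%d", 1:80),
                            catalog)
  # swapping module/background inverts the OR and keeps p
  e2 <- mutation_enrichment(sprintf("b%d", 1:80), sprintf("m%d", 1:50),
                            catalog)
  expect_equal(e1$odds_ratio, 1 / e2$odds_ratio, tolerance = 1e-12)
  expect_equal(e1$p_value, e2$p_value, tolerance = 1e-12)
})

test_that("zero cells trigger the Haldane correction with a warning", {
  catalog <- tibble::tibble(
    cohort_id = "c1",
    gene_id = c(sprintf("m%d", 1:10), sprintf("b%d", 1:10)),
    mutated = c(rep(TRUE, 10), rep(c(TRUE, FALSE), c(5, 5)))
  )
  expect_warning(
    e <- mutation_enrichment(sprintf("m%d", 1:10), sprintf("b%d", 1:10),
                             catalog),
    "Haldane"
  )
  expect_equal(e$odds_ratio, (10.5 * 5.5) / (0.5 * 5.5))
})

test_that("per-gene pooling collapses cohorts before counting", {
  catalog <- tibble::tibble(
    cohort_id = rep(c("c1", "c2"), each = 4),
    gene_id = rep(c("m1", "m2", "b1", "b2"), 2),
    mutated = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  e <- mutation_enrichment(c("m1", "m2"), c("b1", "b2"), catalog,
                           pooling = "gene")
  expect_equal(as.vector(e$table), c(1, 1, 1, 1))
})

test_that("hypergeometric ORA matches exhaustive enumeration on tiny universes", {
  set.seed(5)
  universe <- sprintf("u%02d", 1:12)
  for (i in 1:20) {
    mod <- sample(universe, 5)
    set1 <- sample(universe, 4)
    res <- ora(mod, list(s = set1), universe)
    enum <- ora_enum_oracle(res$overlap, intersect(set1, universe),
                            universe, 5)
    expect_equal(res$p_value, enum, tolerance = 1e-12)
  }
})

test_that("a set disjoint from the module has upper-tail p of 1", {
  universe <- c(sprintf("m%d", 1:5), sprintf("x%d", 1:50))
  res <- ora(sprintf("m%d", 1:5), list(far = sprintf("x%d", 1:10)), universe)
  expect_equal(res$overlap, 0L)
  expect_equal(res$p_value, 1.0)
})

test_that("expected ORA overlap reproduces the platform-scale expectation", {
  universe <- sprintf("g%05d", seq_len(22831))
  module <- universe[1:289]
  set <- universe[c(1:25, 300:353)]  # 79 genes, 25 in the module
  res <- ora(module, list(tcf = set), universe)
  expect_equal(res$expected, 79 * 289 / 22831, tolerance = 1e-12)
  expect_lt(abs(res$expected - 1), 0.05)
  expect_equal(res$overlap, 25L)
  expect_lt(res$p_value, 1e-15)
})

test_that("BH q-values are monotone in p-rank and below Bonferroni", {
  set.seed(6)
  universe <- sprintf("u%03d", 1:200)
  mod <- sample(universe, 40)
  sets <- lapply(1:8, function(i) sample(universe, sample(5:50, 1)))
  names(sets) <- sprintf("set%d", 1:8)
  res <- ora(mod, sets, universe)
  expect_true(all(diff(res$q_value) >= -1e-12))
  expect_true(all(res$q_value <= pmin(1, res$p_value * nrow(res)) + 1e-12))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
})
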