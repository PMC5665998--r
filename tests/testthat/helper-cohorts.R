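# Fixture builders shared across the suite. Everything is generated in code.

# Minimal annotation for n_patients x 4 sites.
make_annotation <- function(n_patients = 8, sites = c("O1", "D1", "D2", "T")) {
  pats <- sprintf("P%02d", seq_len(n_patients))
  sample_annotation(tibble::tibble(
    patient_id = rep(pats, each = length(sites)),
    site = rep(sites, n_patients),
    sample_id = paste0(rep(pats, each = length(sites)), "_",
                       rep(sites, n_patients))
  ))
}

# Site-signature block cohort: n_modules gene blocks, block m elevated in
# exactly one site (cycling O1, D1, D2, T) by a module-specific effect
# (effect + 1.5 * (m - 1), so same-site modules stay distinguishable), plus
# tiny Gaussian noise. Sample rows then fall into exactly four site groups,
# so the co-clustering sample partition can match the proximity annotation
# exactly, while Ward agglomeration can recover all planted modules.
make_block_cohort <- function(seed, n_patients = 8, n_modules = 6,
                              module_size = 30, effect = 3, noise = 1e-3) {
  set.seed(seed)
  ann <- make_annotation(n_patients)
  sites <- c("O1", "D1", "D2", "T")
  n_g <- n_modules * module_size
  expr <- matrix(rnorm(n_g * nrow(ann), 0, noise), n_g, nrow(ann),
                 dimnames = list(sprintf("G%04d", seq_len(n_g)),
                                 ann$sample_id))
  target <- rep(sites, length.out = n_modules)
  for (m in seq_len(n_modules)) {
    idx <- ((m - 1) * module_size + 1):(m * module_size)
    hit <- ann$site == target[m]
    expr[idx, hit] <- expr[idx, hit] + effect + 1.5 * (m - 1)
  }
  list(expr = expr, annotation = ann,
       truth_module = rep(0:(n_modules - 1), each = module_size))
}

# Random gene/sample names for small matrices.
rand_matrix <- function(seed, n_genes, n_samples, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, 0, sd), n_genes, n_samples,
         dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                         sprintf("S%03d", seq_len(n_samples))))
}

# O(n^2) pair-counting adjusted Rand oracle: classifies every element pair
# as agreeing/disagreeing in each partition and applies the chance-corrected
# index definition directly.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b)
  n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b)
  n01 <- sum(!same_a & same_b)
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == expected) return(1)
  (n11 - expected) / (max_index - expected)
}

# Brute-force micro-AUC oracle: average over all (positive, negative)
# element pairs of the flattened matrices, ties counting one half.
micro_auc_oracle <- function(indicator, scores) {
  lab <- as.vector(indicator)
  sc <- as.vector(scores)
  pos <- sc[lab == 1]
  neg <- sc[lab == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Direct evaluation of the Yates-corrected chi-square, odds ratio and Woolf
# interval for a 2x2 table given as counts (a, b, c, d). The continuity
# correction is clamped at the observed deviation (statistic 0 when
# |ad - bc| <= n/2), the standard convention.
yates_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  chi2 <- n * max(abs(a * d - b * c) - n / 2, 0)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  or <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(chi2 = chi2, p = p, or = or,
       ci = exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se))
}

# Exhaustive hypergeometric oracle: enumerates all subsets of the universe
# of the module's size and counts those whose overlap with the set reaches
# the observed one. Only feasible for |universe| <= 15.
ora_enum_oracle <- function(overlap, set_in_universe, universe, module_size) {
  stopifnot(length(universe) <= 15)
  draws <- utils::combn(universe, module_size)
  hits <- apply(draws, 2, function(dr) {
    length(intersect(dr, set_in_universe)) >= overlap
  })
  mean(hits)
}
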