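---
title: "Mapping transcriptomic field cancerization along breast ducts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transcriptomic field cancerization along breast ducts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ductfield)
```

## The study design this package models

Each patient in a ductoscopy-sampled cohort contributes four epithelial
samples ordered by proximity to the tumour: a contralateral-duct baseline
(O1), two samples along the involved duct (D1, D2) and the tumour itself
(T). The package encodes proximity as the ordinal rank O1 = 0 < D1 = 1 <
D2 = 2 < T = 3. Equal spacing of the ranks is the minimal assumption for an
ordinal site code; the mapping is a plain named vector and can be
overridden everywhere it is consumed.

The central scientific questions are (i) whether the spatial perturbation
in expression is attributable to copy-number alterations, (ii) whether
expression alone can place a sample relative to the tumour, and (iii)
which gene modules carry the proximity signal and whether they are
enriched for somatic mutations and signalling pathways.

## Contralateral residualization and CNA variance explained

For every QC-passing duct or tumour sample `s` of patient `p`, an ordinary
least-squares fit across genes

    x(g, s) = a + b * x(g, O1_p) + r(g, s)

treats the patient's contralateral profile as the predictor. The residuals
`r(·, s)` retain the component of expression not shared with the
patient's baseline — the spatial perturbation plus noise. Design choices:

* The regression is *within one sample across genes*, one fit per sample,
  not per-gene across samples; each sample therefore gets its own
  intercept, slope and R².
* An intercept is included in both regressions: log2 offsets between
  arrays are expected and harmless to absorb.
* Tumour samples are residualized like duct samples; O1 samples carry no
  residuals by construction. Patients without a QC-passing O1 are skipped
  with a warning rather than aborting the cohort.

`cna_variance_explained()` then regresses each sample's residual vector on
the same sample's gene-level CNA log-ratios over the expression∩CNA gene
intersection (at least 10 genes) and reports R², slope and intercept. A
zero-variance CNA vector yields R² = 0 with a warning rather than an
error, because degenerate aCGH profiles occur in practice. R² is invariant
to affine rescaling of the CNA values, so the unit of the log-ratio does
not matter.

## Proximity classification

**Feature ranking.** Mutual information between a continuous expression
vector and the discrete site label is estimated with the nearest-neighbour
estimator for mixed continuous/discrete pairs: for each sample the
distance to its k-th nearest neighbour *within the same class* defines a
radius, `m_i` counts the neighbours of any class inside that radius, and

    MI = digamma(N) - <digamma(N_class)> + digamma(k) - <digamma(m_i)>

Negative estimates are clipped to zero; constant genes score exactly zero.
`k = 3` by default, clamped per training fold so it stays below the
smallest class count. A seeded jitter of relative magnitude 1e-10 breaks
ties between identical values; because it scales with the gene's standard
deviation, the estimate is exactly invariant to monotone affine
transforms of a gene.

At n = 32 samples the estimator is noisy: its null 95th percentile is
roughly 0.13 nats, falling to about 0.05 nats at n = 512. Property tests
of the null therefore use n = 512, where a 0.05-nat bound is honestly
attainable; the injective-gene check uses the cohort-sized n = 32 against
the label entropy ln 4 with the estimator's finite-sample tolerance.

**Classifier.** One soft-margin linear support-vector scorer per site
class against the rest (penalty C = 1 by default — no value is canonical,
so it is exposed), on per-gene z-scored features with training-fold
statistics. Classes absent from a training fold are ranked below every
scored class. Cross-validation is leave-one-patient-out: each fold holds
out one patient's full site set, so no patient contributes to both sides
of a fold. MI selection and standardization are recomputed inside each
training fold by default (honest protocol); `select_within_fold = FALSE`
reproduces the one-shot global selection variant.

**Micro-averaging.** The one-hot indicator matrix and the decision-score
matrix are flattened into a single binary problem over all N×K cells. The
AUC is the Mann–Whitney statistic with ties counting one half, which makes
`auc(scores) + auc(-scores) = 1` an exact identity and lets an O(N²)
pairwise-comparison oracle verify the implementation to 1e-12.

**A structural ceiling worth knowing about.** Under the synthetic
generator below, every class mean lies on a single line in gene space
(mean expression = rank × a fixed direction). Any linear functional is
monotone along that line, so a one-vs-rest *linear* scorer can rank the
extreme classes (O1, T) perfectly but cannot isolate the middle ranks
(D1, D2): their one-vs-rest AUC hovers near chance and the pooled
micro-AUC plateaus around 0.85 even when the gradient is several times the
noise — and near 0.72 in the noiseless limit, where the collinearity is
exact. This is a property of the generative geometry, not of the
implementation: a cohort with site-specific (non-collinear) signatures is
classified essentially perfectly by the same code. It also suggests that a
cross-validated micro-AUC in the 0.7–0.8 range on real duct cohorts is
about what a purely monotone shared gradient can deliver.

## Module discovery

MI-selected genes (top 30 % by default) are agglomerated bottom-up with
Ward linkage on Euclidean distances between gene profiles (`ward.D2`, the
variant whose objective is the within-cluster variance increase on raw
Euclidean distances). Modules are renumbered 0..k−1 by first member gene
in gene-id order, so the labelling is deterministic.

The samples × modules summary matrix holds the mean per-gene z-score of
each module in each sample. The mean of z-scores is used because no
summary is canonical; an eigengene variant would be a drop-in replacement
and the matrix interface does not change.

**Bipartite spectral co-clustering.** The summary matrix is shifted by its
global minimum (the spectral normalization needs non-negative weights and
z-score summaries are signed; the shift leaves the partitions invariant,
which is tested), normalized as `An = Dr^{-1/2} A Dc^{-1/2}`, and the
`ceil(log2 nb)` singular-vector pairs after the first are kept. Rows embed
as `Dr^{-1/2} U`, columns as `Dc^{-1/2} V`; the stacked embedding is
k-means clustered (10 restarts, seeded) and rows and columns inherit the
joint labels — each sample and each module belongs to exactly one
bicluster. If a bicluster ends up empty on either axis the clustering is
re-seeded, with an error after 10 attempts.

The number of biclusters defaults to 4, the number of site classes, since
the sample side of the bipartite graph is expected to organise by
proximity; it is a plain argument.

**Choosing k.** For each k in the grid (2–40 by default, bracketing
realistic module counts), the pipeline agglomerates, summarises,
co-clusters, and scores the sample partition against the proximity
annotation with the adjusted Rand index (chance-corrected pair agreement;
computed from the contingency-table formula and verified against an O(n²)
pair-counting oracle and an independent implementation). k* is the argmax,
smallest k on ties. Grid points where the requested bicluster count is
infeasible (k below the bicluster count, or a degenerate clustering) are
recorded as NA rather than aborting the curve — with gradient-only
structure the module axis often supports only two natural groups, and
partial curves are the honest output.

## Module statistics

**Correlation table.** Per module, Pearson correlation between the module
score and the proximity rank; two-sided p from `t = r·sqrt((n−2)/(1−r²))`
on n−2 degrees of freedom; Bonferroni adjustment as `p × m` *without
capping at 1*, with significance read as adjusted p < 0.05. Uncapped
adjusted values above 1 are deliberately reported as-is — they make the
multiplicity burden visible in the table. Zero-variance module scores get
p = 1 with a warning.

**Mutation enrichment.** Module genes versus background genes in a 2×2
table of mutated/not-mutated, restricted to genes present in the
catalogue. The counting unit defaults to the (gene, cohort) pair pooled
across cohorts, matching the idea of evidence accumulating over
independent patient cohorts; a per-gene collapse (`pooling = "gene"`) is
available. Yates-corrected χ² (continuity correction clamped at the
observed deviation, so near-null tables score 0), odds ratio `ad/bc`, and
the Woolf log-scale interval `exp(ln OR ± z·sqrt(1/a+1/b+1/c+1/d))`. A
zero cell triggers the Haldane 0.5 correction for the OR and CI with a
warning; a zero margin is an error.

**Over-representation.** Upper-tail hypergeometric p per gene set against
a fixed universe (default: all genes on the platform after probe
collapse, since no universe is canonical), Benjamini–Hochberg q across
sets, with the expected overlap `set × module / universe` reported so
"25 observed vs ~1 expected"-style statements are directly readable from
the table.

## Quality control

The per-sample QC statistic is a sum of standardized squared errors,
`E(s) = Σ_g (x(g,s) − mean_g)² / (sd_g² + δ)` with δ = 1e-8 guarding
constant genes, flagged above the Tukey upper fence Q3 + 1.5·IQR. The
statistic is invariant to gene order and to per-gene constant shifts, and
a dispersion-inflated sample (the generator's outlier model multiplies the
noise, it does not shift the mean) separates cleanly. Whether such a
rule should standardize by the gene variance or use raw squared errors is
not decidable from its usual one-line description, so
`standardize = FALSE` switches to raw squared error and the fence
multiplier is exposed. One caveat measured during
development and frozen into the tests: on perfectly homogeneous Gaussian
cohorts the 1.5·IQR fence still flags ~0.3–3 % of samples (fence
estimation noise at small n), so "zero false flags in ≥95 % of cohorts" is
not a property this rule can deliver; a fence of 3 would, at the cost of
sensitivity.

## The synthetic cohort generator

`simulate_cohort()` draws, for `n_patients` × 4 sites:

    x(g, s) = baseline(p(s), g)
            + sqrt(1 − c) · slope(g) · rank(s)      # direct gradient
            + beta · cna(g, s)                       # CNA-coupled gradient
            + eps(g, s)                              # N(0, noise_sd)

* `baseline` is gene-wise N(0, patient_sd), shared across the patient's
  four samples — exactly the structure the contralateral residualization
  assumes and removes.
* `slope(g)` is the planted per-module gradient (log2 per rank), signed;
  a scalar `gradient_effect` is recycled with alternating signs so the
  cohort carries both up- and down-regulated modules.
* The CNA matrix holds, for module genes, a rank-proportional dosage with
  gene weights drawn N(0,1) and centred within each module (so the direct
  and coupled components are exactly orthogonal across genes), plus sparse
  background events at rate `cna_event_rate` for every gene.
* `beta` is calibrated numerically so the coupled component contributes
  exactly `cna_coupling` of the total gradient variance over duct entries.
  Because the coupled part of expression is literally `beta × CNA`, the
  per-sample residual-on-CNA regression recovers `cna_coupling` as its R²
  in the low-noise limit — the parameter is directly recoverable, which is
  what makes it a useful test dial.
* Mutation catalogues draw per-(gene, cohort) indicators with baseline
  rate `mutation_rate` for background genes and the planted odds ratio
  `mutation_or` for module genes, over `n_cohorts` cohorts.
* Outliers multiply a sample's noise term by `outlier_factor`; they do not
  shift its mean, matching the dispersion-based QC statistic.

Defaults are 8 patients × 4 sites, 2000 genes, 4 modules × 50 genes,
gradient 1.0 log2/rank, noise 0.5, patient baseline 1.0, CNA coupling 0.2,
event rate 0.05, mutation OR 1.5 over 8 cohorts. The patient, site and
cohort counts mirror the ductoscopy study design; the gene count and the
simulation sizes used by the tests and the acceptance script (150–5200
genes, 3–50 seeds per property) are the package's own choice of
desk-scale problems on which the estimators' convergence windows are known.
The real gradient magnitude is not estimable from published summaries, so
the defaults are property-test placeholders, not estimates of the real
effect size.

What the generator deliberately does **not** emulate: probe-level array
structure (inputs are post-collapse gene matrices), segmented aCGH
profiles (CNA is an idealised gene-level dosage), heavy-tailed or
batch-structured noise, correlated gene–gene backbone outside the planted
modules, and site-specific (non-monotone) expression programs. Passing
tests therefore demonstrate parameter recovery under a clean monotone
field model — they do not certify performance on real arrays, and the
linear-gradient classification ceiling discussed above is one concrete
way the clean model differs from real cohorts.

A second constructed fixture — the site-signature block cohort used in the
module-selection tests, with six gene blocks each elevated in exactly one
site by a block-specific effect — exists precisely because sign-only
gradient modules give the module axis only two natural groups: a
four-bicluster sample partition can then never match the four-site
annotation, whereas block signatures make full recovery (sample ARI 1.0,
gene-module ARI 1.0) attainable and testable.

## Numerical conventions

* PCA components are sign-fixed so each component's largest-magnitude gene
  loading is positive; the variance filter ranks by sample variance
  (denominator n−1) with ties broken by gene id.
* ROC curves are step curves from (0,0) to (1,1); tied scores collapse to
  one point, consistent with the half-credit AUC.
* Probe collapse is the plain arithmetic mean over a gene's probes with no
  variance or expression filtering; ambiguous probe→gene mappings are an
  error, and missing values are rejected rather than imputed (imputation
  would silently move every downstream statistic).
* All stochastic steps (jitter, k-means restarts, simulation) consume an
  explicit integer seed, and derived seeds stay within the 32-bit range;
  every command-line invocation is byte-reproducible for a fixed seed.

## Known limitations

* The co-clustering returns NA at grid points whose bicluster count the
  matrix cannot support; ARI curves over gradient-only cohorts are
  typically partial.
* The Woolf interval is asymptotic; at very small cell counts the Haldane
  correction stabilises the point estimate but the interval remains
  approximate.
* The MI estimator's finite-sample spread at 32 samples is substantial
  (±0.1 nats); rankings are useful, absolute MI values at cohort size are
  not.
* Pearson correlation against an equally spaced ordinal rank is a
  modelling choice; a rank-based association would be the robust
  alternative and can be computed from the same summary matrix.
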