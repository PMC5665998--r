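# ductfield

Spatial mapping of transcriptomic field cancerization along breast ducts.

## The problem

Histologically normal epithelium surrounding a breast tumour is not
molecularly normal: acquired perturbations extend over a geographic region
of tissue around the lesion (*field cancerization*). `ductfield` implements
an analysis pipeline for patient-matched cohorts in which each patient
contributes epithelial samples at increasing proximity to the tumour — a
contralateral-duct baseline (O1, proximity rank 0), two samples along the
involved duct (D1 = 1, D2 = 2) and the tumour itself (T = 3) — with matched
gene-level copy-number (aCGH) log-ratios and public mutation catalogues.

The pipeline answers, in order:

1. **Is the spatial signal in expression explained by copy number?**
   Each duct/tumour profile is residualized on the same patient's
   contralateral profile across genes,
   `x(g, s) = a + b·x(g, O1_p) + r(g, s)`, and the residual vector is then
   regressed on the sample's own CNA log-ratios; the per-sample R² measures
   how much of the spatial perturbation copy number explains.
2. **Is expression informative about proximity at all?** Genes are ranked
   by a nearest-neighbour mutual-information estimate against the site
   label, the top fraction feeds one-vs-rest linear support-vector scorers,
   and performance is summarised by the micro-averaged ROC/AUC (every cell
   of the one-hot label matrix treated as one binary prediction) under
   leave-one-patient-out cross-validation.
3. **Which gene modules track proximity?** MI-selected genes are
   agglomerated by Ward clustering into k modules; the samples × modules
   mean-z-score matrix is bipartitely spectral co-clustered
   (`An = Dr^-1/2 A Dc^-1/2`, trailing singular vectors, joint k-means);
   k is chosen to maximise the adjusted Rand index between the sample
   partition and the proximity annotation.
4. **Are those modules biologically loaded?** Per-module Pearson
   correlation with proximity rank, two-sided p from
   `t = r·sqrt((n-2)/(1-r²))`, *uncapped* Bonferroni adjustment
   (adjusted values above 1 are reported as-is); mutation enrichment of
   module genes versus background by Yates-corrected χ² with the odds
   ratio's Woolf interval; pathway over-representation by upper-tail
   hypergeometric tests with Benjamini–Hochberg q-values.

A synthetic cohort generator (`synthetic_config()` / `simulate_cohort()`)
plants known gradients, CNA coupling, outliers and mutation enrichment so
every stage has a parameter-recovery test surface.

## Worked example

```r
library(ductfield)

co <- simulate_cohort(synthetic_config(gradient_effect = 1.5, seed = 3))
co
#> Synthetic patient-matched cohort
#>   genes:    2000
#>   samples: 32 (8 patients x 4 sites)
#>   planted modules: 4 of size 50
#>   cna_coupling: 0.2  mutation OR: 1.5

# how much of the duct residual variance does copy number explain?
res <- residualize_on_contralateral(co$expr, co$annotation)
ve  <- cna_variance_explained(res, co$cna)
mean(ve$r_squared)
#> [1] 0.1214823

# can expression place a sample relative to the tumour?
cv <- lopo_cv(co$expr, co$annotation, seed = 3)
cv
#> Leave-one-patient-out proximity classification
#>   folds:           8
#>   mean fold AUC:   0.865
#>   pooled microAUC: 0.856
glance(cv)       # micro_auc, mean_fold_auc, n_folds
autoplot(cv)     # pooled micro-averaged ROC curve
```

The mean duct R² near 0.12 reflects the planted condition that only a
fifth of the gradient variance is routed through copy number and the rest
is diluted by noise: copy number explains little of the spatial
perturbation. The cross-validated micro-AUC well above 0.5 shows the
expression profile alone carries the proximity signal.

Module discovery and the correlation table:

```r
sel  <- mi_rank(co$expr, co$annotation$site, fraction = 0.30, seed = 3)
es   <- co$expr[sel$gene_id[sel$selected], ]
ms   <- choose_module_count(es, co$annotation, k_grid = 4:24,
                            n_biclusters = 4, seed = 3)
summ <- module_summary_matrix(es, ms$best)
correlate_modules(summ, co$annotation)
#> # A tibble: ... module, pearson_r, p_value, p_bonferroni, significant, ...
```

`p_bonferroni` is `p_value * m_tests` without capping, and significance is
read as `p_bonferroni < 0.05`.

## Command line

A thin `fieldmap` front end wraps the same functions:

```sh
FIELDMAP=$(Rscript -e 'cat(system.file("scripts/fieldmap.R", package = "ductfield"))')
Rscript $FIELDMAP simulate --config cfg.yaml --seed 17 --out sim/
Rscript $FIELDMAP qc         --expr sim/expression.tsv --out qc/
Rscript $FIELDMAP residualize --expr sim/expression.tsv \
        --samples sim/samples.tsv --cna sim/cna.tsv --out res/
Rscript $FIELDMAP classify   --expr sim/expression.tsv \
        --samples sim/samples.tsv --seed 17 --out cls/
Rscript $FIELDMAP comodule   --expr sim/expression.tsv \
        --samples sim/samples.tsv --kmin 4 --kmax 24 --seed 17 --out mod/
```

All commands are deterministic for a fixed `--seed`: two runs produce
byte-identical artefacts.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "ductfield",
                               load_package = "installed")'
```

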