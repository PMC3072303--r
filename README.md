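# cadscore

Development pipeline for a whole-blood gene-expression classifier of
obstructive coronary artery disease (CAD), implemented as a tested R
package.

## Background

Obstructive CAD is conventionally confirmed by invasive coronary
angiography, yet a large fraction of patients referred to catheterization
turn out not to have it. Circulating blood cells change their gene
expression in the presence of coronary atherosclerosis — neutrophil
activation up, specific lymphocyte programs down, with effects that differ
by sex — which makes a quantitative RT-PCR score from a routine blood draw
an attractive non-invasive gatekeeper.

This package implements the statistical machinery used to develop such a
score in non-diabetic patients, from microarray discovery through a locked
real-time-PCR algorithm:

* **Discovery**: trimmed-mean normalization, array QC, per-gene logistic
  association (unpaired, sex/age-adjusted, robust), conditional logistic
  regression for age/sex-matched case:control pairs, Benjamini–Hochberg
  FDR, cross-cohort intersection, hypergeometric enrichment, clinical
  factor tests.
* **Panel selection**: correlation clustering (average linkage on
  `1 − r`), cell-type annotation from blood-count and marker correlations,
  normalization-gene screening, greedy panel assembly.
* **Algorithm development**: meta-genes (equal-weighted sets of 1–4
  correlated genes), ratio terms (log-scale meta-gene differences), LASSO
  term selection with sex interactions, Ridge final fits with a linear male
  age term and a female hinge-age term `max(age − 60, 0)`, leave-one-out
  cross-validated ROC evaluation.
* **The locked score**: six ratio terms over 23 genes (20 informative + 3
  normalization), with Term 2 normalized to RPL28 in men and AQP9/NCF4 in
  women and a male-only Term 6. The score is
  `intercept + Σ w_t·term_t + β_m·age·I(male) + β_f·max(age−60,0)·I(female)`.
* **Synthetic cohorts**: a generator with latent cell-type factors, shared
  lymphoid structure, sex-dependent (including sign-reversed) disease
  effects, a diabetic attenuation mechanism, and triplicate RT-PCR
  measurement noise — plus a Monte-Carlo Bayes-optimal AUC oracle, so every
  pipeline stage is validated against known ground truth.

The published clinical coefficients are not in the public record; the
package ships clearly-non-clinical default coefficients derived from a
packaged synthetic reference cohort, and accepts user-supplied
coefficients for all scoring functions. Nothing here is a medical device.

## Worked example

```r
library(cadscore)

counts <- locked_structure_counts()
unlist(counts)
#>         n_panel_genes            n_clusters           n_metagenes
#>                   113                    18                    15
#>               n_terms     n_algorithm_genes   n_informative_genes
#>                     6                    23                    20
#> n_normalization_genes
#>                     3

# score a fresh synthetic cohort with the locked algorithm
sim   <- locked_reference_cohort(n = 300, seed = 7)
batch <- score_batch(sim$expr, sim$samples)
head(batch[, c("id", "sex", "age", "score")], 3)
#>          id sex      age     score
#> S0001 S0001   F 55.73167  0.510229
#> S0002 S0002   M 73.16760  3.048737
#> S0003 S0003   M 49.11970 -1.944113
roc <- attr(batch, "roc")
sprintf("AUC %.3f (95%% CI %.3f-%.3f)", roc$auc, roc$ci_low, roc$ci_high)
#> [1] "AUC 0.966 (95% CI 0.948-0.984)"

# the same transcript profile scores differently by sex: Term 2 switches
# denominator, Term 6 drops out, and the age term changes form
x <- setNames(unclass(sim$expr)[, 1], rownames(sim$expr))
compute_locked_score(x, "M", 65)   #> 2.876
compute_locked_score(x, "F", 65)   #> 0.890

# matched-pair conditional logistic regression on pair differences
d   <- c(0.8, -0.3, 1.2, 0.5, -0.1, 0.9, 0.4, -0.6, 1.1, 0.2)
fit <- clogit_1to1(d)
sprintf("beta %.4f (se %.4f), score test p %.4f", fit$beta, fit$se, fit$p_score)
#> [1] "beta 2.1810 (se 1.3801), score test p 0.0670"
```

## Analysis workflow

The `analysis/` directory holds numbered drivers that narrate the full
pipeline on synthetic data, writing tables to `results/`:

```sh
Rscript analysis/01_simulate.R        # cohort + RT-PCR measurement model
Rscript analysis/02_discovery.R      # QC, association, pairs, enrichment
Rscript analysis/03_panel_selection.R
Rscript analysis/04_algorithm_fit.R  # LASSO/Ridge, LOOCV vs Bayes oracle
Rscript analysis/05_locked_score.R
```

All computation lives in the package under `R/`; the drivers only
orchestrate and write outputs.

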