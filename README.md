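# methdex

Gene-level scoring of DNA methylation and a methylation-derived depression
index (mDI), with a downstream per-year breast-cancer risk model.

## The problem

Illumina 450K-style arrays report per-CpG methylation fractions (beta
values). Promoter methylation and gene-body methylation relate to
expression in opposite ways, so a useful *gene-level* summary is the
statistical contrast between a gene's promoter probes and its body/UTR
probes within one sample. `methdex` implements that contrast — the **SIMPO
score**, a pooled two-sample t-statistic

$$t \;=\; \frac{\bar x - \bar y}{S_w\sqrt{1/m + 1/n}},\qquad
S_w^2 \;=\; \frac{(m-1)S_1^2 + (n-1)S_2^2}{m+n-2},$$

where $\bar x, S_1^2, m$ summarise the promoter-probe betas (TSS1500/TSS200)
and $\bar y, S_2^2, n$ the other-region betas (5'UTR, 1stExon, Body, 3'UTR)
— and builds from it a case/control index for depression:

1. **Resampling selection** — subsample 90% of the cohort (stratified,
   without replacement) 300 times; in each iteration rank genes by the
   p-value of a case-vs-control t-test of their SIMPO scores and count how
   often each gene enters the top 50.
2. **mDI** — split the top *K* genes by the sign of their average t-score
   into "positive" and "negative" sets; a sample's index is
   $\mathrm{mDI} = 1 + (\bar x - \bar y)\big/\sqrt{S_x^2/n + S_y^2/m}$, a
   Welch-style contrast of the sample's SIMPO scores over the two sets.
3. **K sweep** — compute the point-biserial correlation between mDI and
   case status for every $K \in [10, 500]$ and freeze the model at the
   maximum.
4. **Evaluation** — correlation, pooled t-test, ROC/AUC, median-split and
   quartile odds ratios on training and held-out cohorts.
5. **Cancer risk model** — combine the frozen index with blood
   cell-proportion covariates (monocytes, granulocytes, lymphocytes,
   CD4/CD8 ratio, NLR, MLR), z-scored per modelling subset, in a
   p-value-guided bidirectional stepwise logistic regression with pairwise
   interactions, per cumulative follow-up year; plus a random-forest
   comparator with permutation importances.

A seeded synthetic cohort generator emulates the probe/gene structure,
causal promoter shifts in either direction, blood cell proportions and a
time-to-diagnosis outcome, so the entire pipeline is testable without any
external download. It is aimed at epigenomics researchers who want a
transparent, reproducible reference implementation of this class of
methylation risk scores.

## Worked example

```r
library(methdex)

sim <- simulate_methylation_cohort(n_cases = 150, n_controls = 150,
                                   n_genes = 500, n_causal = 30,
                                   effect_size = 0.25, seed = 42)
idx <- build_gene_region_index(sim$annotation, sim$beta)
sm  <- simpo_matrix(sim$beta, idx)
fit <- mdi_fit(sm, sim$phenotype$label, n_iter = 100,
               k_min = 10, k_max = 200, seed = 43)
fit
#> Methylation-derived depression index (mDI) model
#>   k = 52 genes: 22 positive, 30 negative
#>   training point-biserial r = 0.804
#>   selection: 100 iterations x 90 % subsamples, top 50 (seed 43)

## apply the frozen model to an independent cohort of the same generative law
test <- simulate_methylation_cohort(n_cases = 150, n_controls = 150,
                                    n_genes = 500, n_causal = 30,
                                    effect_size = 0.25, truth = sim$truth,
                                    seed = 44)
sm_test <- simpo_matrix(test$beta,
                        build_gene_region_index(test$annotation, test$beta))
scores  <- predict(fit, sm_test)
evaluate_index(scores$mdi, test$phenotype$label, n_boot = 500, seed = 45)
#> Index evaluation ( 150 cases / 150 controls )
#>   point-biserial r = 0.669 (p = 2.64e-40)
#>   two-sample t = 15.542 (p = 2.64e-40)
#>   AUC = 0.899 [0.867, 0.932]
#>   OR (median split) = 17.41 [9.81, 30.88]
#>   OR (Q4 vs Q1)     = 204.12 [55.20, 754.89]
#>   OR per SD (logistic) = 12.90
```

The fitted model settles on 52 genes (22 whose promoter-vs-body contrast
rises in cases, 30 that fall). On the held-out cohort the frozen index
separates cases from controls with AUC 0.899; a sample in the top half of
the index distribution has about 17-fold higher odds of being a case than
one in the bottom half. The 30 causal genes here carry a deliberately
moderate promoter shift (0.25 on the logit scale); larger shifts drive the
held-out AUC toward 1.

For the cancer arm, `simulate_cancer_cohort()` attaches cell proportions
and per-year diagnoses to a scored cohort and `fit_cancer_risk()` returns
the per-year stepwise fits, quartile odds ratios, random-forest AUC and the
pseudo-R² contribution of the index (see `?fit_cancer_risk`).

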