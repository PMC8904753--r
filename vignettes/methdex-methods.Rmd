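---
title: "Methods: the SIMPO score, the mDI index and the downstream risk model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SIMPO score, the mDI index and the downstream risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdex)
```

# Overview

`methdex` turns probe-level 450K-style methylation data into a per-gene,
per-sample contrast score (SIMPO), selects case-associated genes by
resampling, combines them into a single index (mDI), and feeds the index
into a per-year logistic risk model for a prospective outcome. This
vignette documents the statistical model behind each stage, the tunable
parameters, the numerical choices made at the edges, and what the synthetic
cohorts used by the tests do and do not establish.

# The SIMPO score

For gene $g$ and sample $s$, let $x_1,\dots,x_m$ be the beta values
(methylation fractions, unitless in $[0,1]$) of the probes annotated to the
gene's promoter (manifest groups TSS1500 and TSS200) and $y_1,\dots,y_n$
those of its other regions (5'UTR, 1stExon, Body, 3'UTR). The score is the
pooled two-sample t-statistic

$$t_{gs} = \frac{\bar x - \bar y}{S_w\sqrt{1/m + 1/n}},\qquad
S_w^2 = \frac{(m-1)S_1^2 + (n-1)S_2^2}{m+n-2},$$

with unbiased (count $-$ 1) variances. It is a *descriptive* contrast —
no p-value is attached; the score is carried forward as a quantitative
trait.

Choices at the edges:

* **Promoter definition.** The promoter side is the two TSS manifest
  groups; everything else is "other". Region membership comes from the
  annotation labels only — genome coordinates and strand never enter.
* **Dual-annotated probes.** A probe annotated to both a promoter and a
  non-promoter group of the same gene contributes to *both* sides. The
  manifest genuinely multi-labels probes; dropping them would silently
  shrink $m$ and $n$.
* **Minimum probes.** Genes need at least 2 probes per side
  (`min_probes = 2`): both variance terms are undefined for singletons.
* **Missing values** are dropped per (gene, sample, side), not imputed, so
  the effective $m, n$ vary by sample. A cell with fewer than 2 remaining
  values on either side, or with $S_w = 0$, is *invalid* (`NA`): a
  constant-methylation gene carries no contrast, and an infinite t cannot
  be consumed downstream. Genes invalid in more than 5% of samples
  (`max_invalid_frac`) are dropped with a warning.
* **Precision.** The matrix path uses two-pass (centred) variances so it
  agrees with the scalar definition to better than $10^{-10}$; the tests
  assert exactly that against an independently coded oracle.

# Resampling gene selection

Each of `n_iter = 300` iterations draws `fraction = 0.9` of the samples
without replacement — a fresh draw per iteration, *stratified by
case/control label* so both classes keep their marginal proportion
(unstratified draws can produce degenerate class imbalance in small
cohorts). Within an iteration, every gene gets a two-sided pooled-variance
t-test of case vs control SIMPO scores; the `top_n = 50` genes by ascending
p enter that iteration's top list. Ties in p are broken by $|t|$
descending, then gene symbol, making the ranking deterministic.

The selection output per gene is its **occurrence count** (iterations in
the top list) and its **mean t** over *all* iterations. Averaging over all
iterations rather than only top-list appearances avoids biasing
$|\bar t|$ upward — every iteration computes genome-wide t-scores anyway,
and the mean's role is only to estimate the population *sign* of the
gene's effect. Genes with fewer than two valid cells in a class receive
the sentinel $t = 0, p = 1$ so they sort last.

# The mDI index and the K sweep

The top $K$ genes are split by the sign of their mean t into a positive
set ($n$ genes) and a negative set ($m$ genes); an exact zero goes to the
positive side (documented tie rule; in practice zeros do not occur). A
sample's index contrasts its SIMPO scores over the two sets with a
Welch-style denominator:

$$\mathrm{mDI} = 1 + \frac{\bar x - \bar y}
{\sqrt{S_x^2/n + S_y^2/m}}.$$

The Welch form is kept deliberately distinct from the pooled SIMPO form,
and the "1 +" offset is kept verbatim so that $\mathrm{mDI} = 1$ means no
contrast. A sample with fewer than two valid genes on either side is
flagged `NA`, never silently scored.

$K$ is swept inclusively in steps of 1 from `k_min = 10` to `k_max = 500`;
at each $K$ the Pearson correlation (point-biserial) between the index and
the 0/1 label is computed and the model is frozen at the signed maximum —
signed, not absolute, because the sign partition orients the index with
cases high by construction. Ties go to the smallest $K$ (parsimony). The
full curve is returned so a plateau heuristic can be applied by eye where
the maximum sits on a flat stretch. Internally the sweep uses cumulative
sums over the ranked genes, so all $\approx 500$ index vectors are
computed in one pass; the tests check the per-$K$ scores against direct
scoring at $10^{-8}$.

Two regimes of the curve are worth knowing about (both are exercised in
the tests). With a moderate causal effect the curve rises while causal
genes are being added and falls once noise genes dilute the contrast, so
the chosen $K$ tracks the causal gene count. With a very strong effect the
index saturates (every $K$ beyond the causal count discriminates almost
perfectly) and the argmax over the flat stretch is effectively noise —
the curve, not the single number, is the informative output there.

**Validation transfers the frozen model.** Scoring a new cohort uses the
frozen gene sets and $K$; nothing is re-selected. Genes absent from the
new cohort are dropped with a warning naming them; a set reduced below two
genes is an error naming the set.

# Evaluation statistics

* Point-biserial correlation with the two-sided p from the t-distribution
  on $n-2$ df. This is mathematically equivalent to the pooled two-sample
  t-test p; the tests assert agreement to $10^{-9}$ as an internal
  cross-check.
* AUC by the Mann–Whitney formulation (midranks; ties count one half),
  checked against brute-force pair counting and against an external ROC
  implementation. A bootstrap percentile CI (2,000 seeded resamples by
  default) replaces an analytic CI.
* Odds ratios in two modes, because a published dichotomization is often
  unrecoverable: a **median split** (ties at the median go low) and **top
  vs bottom quartile** (type-7 empirical quartiles, boundary ties to the
  lower bin). OR $= ad/bc$ with a Woolf log-normal 95% CI; any zero cell
  triggers the Haldane–Anscombe 0.5 correction and is flagged. A per-SD
  logistic OR is reported alongside for a cut-free summary.

# The per-year cancer risk model

For each follow-up year $y \ge 3$ the cohort is the cumulative cases
(diagnosed by year $y$) against the participants cancer-free through the
final follow-up; years with fewer than 10 cases are skipped. The design
has seven predictors — the index plus monocyte, granulocyte and lymphocyte
proportions, the CD4/CD8 ratio, NLR (granulocytes/lymphocytes) and MLR
(monocytes/lymphocytes) — each z-transformed ($z = (x - m)/S$, sample SD)
*on the modelling subset itself*, so every per-year model is scaled on its
own data.

**Stepwise selection.** Candidates are the 7 main effects plus all 21
pairwise products of the z-scored columns. Starting from the intercept,
the candidate with the smallest deviance (likelihood-ratio) p-value enters
while $p < 0.05$ (`p_enter`); after each entry, included terms with
drop-one $p > 0.10$ (`p_remove`) are removed, worst first. The thresholds
mirror the documented defaults of the classical p-value-guided stepwise
GLM tools. Hierarchy is handled the way those tools behave in published
tables: an entering interaction pulls its absent parents in with it, and
parents of an included interaction are protected from removal — which is
why a main effect can legitimately sit in the final table with a large
p-value. Candidates are examined in lexicographic order, so the procedure
is deterministic and invariant to the order candidates are supplied; a
visited-state guard prevents add/remove cycles. Wald statistics are
reported in the coefficient table for comparability with published
layouts, while deviance tests drive the selection itself.

Two calibration facts about this procedure, established by simulation in
the test suite: the *per-candidate* entry test holds its nominal level
(false-entry rate $0.05 \pm 0.02$ over 1,000 single-candidate null
replicates), but with 28 candidates each examined at 0.05 the *family-wise*
probability that at least one noise term enters is roughly
$1 - 0.95^{28} \approx 0.76$, so on a fully null design the procedure
returns a non-empty model most of the time (measured empty-model rate
0.2–0.3 across seed sets). That is an inherent property of p-value-guided stepwise
selection, not an implementation artefact; users who need family-wise
control should tighten `p_enter`.

**Separation.** If any selected coefficient exceeds 15 on the z scale the
fit is flagged and refitted by ridge-penalized IRLS with $\lambda =
10^{-6}$ on the non-intercept terms — enough to bound the estimates
without visibly perturbing a well-posed fit.

**Comparators.** A random forest on the seven main effects reports a
stratified 5-fold cross-validated AUC and a seeded permutation importance:
the mean drop in held-out AUC over 20 within-fold permutations per
predictor, with a normal-approximation CI, reported unclipped. The
contribution of the index is quantified by McFadden pseudo-$R^2$ of the
full model versus the model with the index block (main effect and every
interaction containing it) removed, with the block likelihood-ratio test.

# The synthetic cohort generator

`simulate_methylation_cohort()` emulates exactly the structure the
analysis assumes:

* per gene, 2–8 probes per side (uniform); per probe, a logit-scale mean
  around the side baseline (promoter $-1.0$, other $+0.5$, between-probe
  SD 0.5) — promoters hypomethylated, bodies methylated, as on real
  arrays;
* per sample, independent logit-scale noise (SD 0.5); beta =
  inverse-logit, clipped to $(0.001, 0.999)$ to keep logit transforms
  finite;
* causal genes shift their *promoter* probes by $\pm d$ (logit scale) in
  cases, split 50/50 between directions so both sides of the sign
  partition are exercised. Only the promoter side moves because the score
  contrasts promoter against body — an equal shift of both sides must
  produce no signal, and the tests assert that too;
* default cohort sizes mirror a 324/209 discovery cohort; a `truth`
  argument lets an independently seeded cohort reuse the same causal
  genes and directions, which is how held-out cohorts "of the same
  generative law" are made.

`simulate_cancer_cohort()` draws (mono, gran, lympho, rest) from a
Dirichlet with concentration $(8, 60, 30, 2)$ — means about
0.08/0.60/0.30, typical whole blood — a CD4/CD8 ratio from a log-normal
(median 1.8, log-SD 0.3), and the outcome from
$\operatorname{logit}^{-1}(b_0 + b_{\text{mdi}}\,z(\text{mDI}) +
b_{\text{int}}\,z(\text{mDI})\,z(\text{CD4/CD8}))$ with defaults
$b_{\text{mdi}} = 0.6037$, $b_{\text{int}} = 0.5579$ and $b_0$ set to a
final case fraction of $235/659$; diagnosed samples get a uniform
diagnosis year in 1–11.

**What the generator does not emulate:** probe chemistry (type I/II),
batch and normalization artefacts, detection-p missingness structure,
correlated probe noise within a gene, genome-wide gene counts
($\sim$20,000), and any real biological pathway structure. Passing tests
therefore demonstrate that the *pipeline* recovers what it is designed to
recover under its own assumptions — they say nothing about effect sizes or
discrimination achievable on real cohorts, where reported correlations and
AUCs are far more modest.

# Problem sizes used by the tests

The test suite runs at desk scale, chosen once as the smallest sizes at
which each property is comfortably identified: formula oracles on 1,000
random inputs; signal recovery on one 1,000-gene / 50-causal cohort of
150+150 samples with $d = 1.0$ and 100 resampling iterations; null
calibration on 50 replicates of 200-gene cohorts (train 100+100, held-out
200+200, 25 iterations, $K \in [10, 100]$, 100 permutations); stepwise
power and null behaviour on 100 replicates of $n = 650$ designs plus
1,000 single-candidate replicates. The acceptance script uses a 324/209
discovery cohort, a 98/96 validation cohort and a 659-participant cancer
cohort, all with 1,000 genes and 50 causal at $d = 1.0$.

On held-out *null* cohorts the sweep maximum is compared against a
permutation null built by shuffling the held-out labels. The comparison is
made on held-out data deliberately: on the training cohort the selection
step has already adapted to the labels, so the training-set maximum
exceeds a naive label-shuffle null by construction, and only the held-out
statistic is exchangeable with its permutations.

# Known limitations

* The index is a cross-sectional classifier; no survival/time-to-event
  modelling is attempted (per-year cumulative binary cohorts only).
* Cell proportions are consumed as given covariates; estimating them from
  methylation is out of scope.
* No probe QC, normalization or array-artefact handling — inputs are
  assumed preprocessed.
* Stepwise inclusion p-values are post-selection quantities and inherit
  the usual caveats; the reported per-year tables are descriptive.
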