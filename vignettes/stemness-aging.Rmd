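---
title: "Methods: the stemness index and its aging-association pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the stemness index and its aging-association pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemIndex)
```

# The model

## One-class logistic regression (OCLR)

Transcriptomic "stemness" is quantified by similarity of a bulk expression
profile to pluripotent stem cells. The signature is a per-gene weight
vector $w$ obtained by fitting a one-class logistic model to stem-labeled
training samples: with centered expression profiles $x_i$ and scores
$s_i = w^\top x_i$, we maximize

$$L(w) \;=\; \frac{1}{n}\sum_{i=1}^{n}\Big[s_i - \log(1+e^{s_i})\Big]
\;-\; \frac{\lambda_2}{2}\,\|w\|^2 ,$$

the mean log-probability that each training sample belongs to the positive
class, with a ridge penalty and no intercept. The objective is concave;
`fitOCLR()` maximizes it by fixed-step gradient ascent from $w = 0$ with
step $1/L$, where $L = \lambda_2 + \sigma_{\max}(X)^2/(4n)$ bounds the
gradient's Lipschitz constant ($\sigma_{\max}$ computed by an exact
symmetric eigendecomposition of the smaller Gram matrix). The fixed step
guarantees a monotonically non-decreasing objective trace; convergence is
declared when the gradient max-norm falls below `tol`.

A point that is easy to get wrong: **centering must use the full training
compendium, not the stem samples alone.** If each gene is centered across
exactly the samples the model is fitted on, then $\sum_i x_i = 0$ per gene,
the gradient at $w=0$ vanishes, and $w=0$ is the *global* maximum of the
strictly concave penalized objective — the signature would be identically
zero. `trainStemnessSignature()` therefore centers every gene over all
training columns (pluripotent **and** differentiated) and fits the
one-class model on the stem-labeled subset, which is also how the
published stemness-index lineage trains: against a compendium that
includes differentiated progenitors.

Training operates on $\log_2(\mathrm{TPM}+1)$ by default (`log2 = TRUE`).
Downstream scoring is rank-based, so this choice affects only the
conditioning of the training problem, not the scoring contract.

Defaults: $\lambda_2 = 1$, `tol = 1e-6` on the gradient max-norm,
`maxIter = 10000`. No stochastic initialization is used anywhere, so
training is exactly reproducible and invariant to sample order. Genes with
no variance in training end with weight $\approx 0$ through the penalty;
they are retained (harmless under rank scoring).

## Scoring

A sample's raw score is the Spearman correlation between $w$ and the
sample's expression profile over the genes shared by signature and matrix
(average ranks for ties; at least 3 shared genes required; constant
profiles get `NA` with a warning). Raw scores are mapped to the unit
interval by the cohort min–max:
$\mathrm{stemness}_j = (r_j - r_{\min})/(r_{\max} - r_{\min})$, so 0 and 1
are the least and most stem-like samples *of that scoring cohort*. Because
the map is cohort-dependent, the rescaling scope is an explicit argument:
`"all"` (one pooled map, the pan-tissue convention) or `"per_group"`
(independent maps per dataset, the convention when validation cohorts are
scored separately). Raw scores are always returned so a run can be
re-scoped without re-scoring.

Rank-correlation scoring makes the index invariant under any strictly
increasing transform of a sample's expression values — so TPM-like input
is accepted as-is and never renormalized inside the pipeline.

## Downstream inference

* **Per-tissue age association** (`correlateWithinGroups()`): Pearson
  correlation of stemness with age within each tissue holding at least
  `minN = 50` samples (the display threshold commonly used for
  tissue-level summaries; configurable), p-values from the exact
  $t$-transform with $n-2$ df, Benjamini–Hochberg correction applied
  *across the tissues of one analysis family* (one correction per
  x-variable). Tissues under the threshold are reported as skipped, never
  silently dropped.
* **Covariate-adjusted linear model** (`fitAgeModels()`): per tissue,
  stemness is regressed on age (years, numeric) plus treatment-coded sex,
  Hardy death code, and tissue region. A categorical that is constant or
  entirely missing in a tissue is dropped and recorded (sex in
  sex-restricted tissues, region where there is a single detail). Rows
  missing a retained covariate are dropped (complete-case), not imputed.
  The Hardy code is treated as an opaque categorical, not ordinal. The
  reference level of each categorical is its most frequent level, which
  stabilizes the intercept and is recorded in the output. Fitting is
  ordinary least squares with $t$-based inference — with one response per
  tissue, empirical-Bayes variance moderation has nothing to share
  strength across, so plain OLS is the faithful model. The fold-change
  summary is defined as
  $\log_2 \hat y(75)/\hat y(25)$ at reference covariate levels
  (the extreme decade midpoints); it is reported as undefined, with the
  reason, whenever a predicted stemness is non-positive. This definition
  is a documented package choice: "stemness variation (log2FC)" has no
  canonical formula.
* **Cross-tissue structure** (`subjectTissueMatrix()`,
  `pairwiseCorrelation()`): per subject and tissue the mean stemness of
  that subject's samples (several same-tissue samples average), then
  pairwise-complete Pearson correlations between tissues over shared
  subjects. Pairs with fewer than `minOverlap = 10` shared subjects are
  masked rather than reported (the overlap count is always emitted);
  sex-restricted tissues are excluded up front since they cannot share
  donors of both sexes. Ordering for display comes from average-linkage
  clustering on $1-r$; tissues are sorted lexicographically before
  clustering so equal-distance merges resolve deterministically and the
  leaf order is invariant to input order.
* **Proliferation and senescence** (`geneSetSignal()`,
  `markerSignal()`, `deriveProliferationSet()`): a gene set's per-sample
  signal is the arithmetic mean TPM of its present genes (coverage below
  50% warns; zero coverage errors); a single marker (MKI67) is its raw
  expression row. `deriveProliferationSet()` reproduces the standard
  recipe of taking the top 1% of genes most positively correlated with a
  proliferation marker. Group comparisons use Welch's $t$ for two groups
  (safer than the pooled form under unequal variances; `pooled = TRUE`
  restores the textbook Student test) and Kruskal–Wallis with tie
  correction for three or more.

## Age handling

Donor ages given as decade bins are mapped to midpoints
(20–29 → 25, …, 70–79 → 75) by `ageBinToMidpoint()`, which is total on
exactly those six labels and rejects everything else; literal ages pass
through unchanged. Cultured-cell tissue details (EBV-transformed
lymphocytes, transformed fibroblasts) score as extreme stem-like outliers
and should be removed with `filterTissueDetails()` before tissue-level
aging analyses; both filter-then-score and score-then-filter are possible,
and they differ — the min–max rescaling changes with the cohort — so the
choice is left explicit to the user.

# The synthetic study

`simulateCohort()` and `simulateTrainingCohort()` generate data with known
ground truth so every stage of the pipeline is verifiable offline.

**Generative model.** Expression is log-normal:
$\mathrm{TPM}_{gi} = \exp(b_g + c_g\,\ell_i + \varepsilon_{gi})$ with gene
baselines $b_g \sim N(2, 1)$, noise
$\varepsilon_{gi} \sim N(0, 0.5)$ on the log scale (positivity is
automatic), and a latent per-sample stemness

$$\ell_i = \beta_{\mathrm{age}}(\mathrm{age}_i - 50)
 + \beta_{\mathrm{sex}}\,\mathbf 1[\mathrm{female}]
 + \gamma_{\mathrm{region}} + \lambda_t u_{s(i)} + N(0, 0.8),$$

where $u_s \sim N(0,1)$ is a subject-level shared factor inducing
cross-tissue correlation within a donor. Couplings $c_g$ are 1 for the
100 signature genes, $+0.5$ for the 40 proliferation genes (including the
MKI67 marker), $-0.5$ for the 40 senescence genes, and 0 elsewhere. The
training compendium instead shifts signature genes up by 1.5 log-units in
the 50 pluripotent samples against 100 differentiated samples.

**Default cohort.** Ten tissues of 300 samples each, drawn from a shared
pool of 800 subjects whose ages are uniform over the six decade bins:
eight tissues with $\beta_{\mathrm{age}} = -0.02$/year, a female-only
"uterus" with $+0.02$/year, and a null "muscle"
($\beta_{\mathrm{age}} = 0$). With age spanning 25–75 this calibrates the
observable score–age correlation to roughly $|r| \approx 0.3$ per tissue
— a moderate, realistic effect. "brain" carries zero shared-factor
loading (all others load 0.5), giving the cohort a tissue whose stemness
is decoupled from the rest of the organism; uterus and muscle provide the
qualitative exceptions (direction reversal, null) that the inference
stages must recover rather than assume.

**Seeding.** A single configuration seed fixes the *biology* (which genes
form the signature and the gene sets, their baselines), while the
replicate seed passed to the simulators drives the *sampling* (subjects,
noise) through per-component substreams. Repeated cohorts drawn with
different replicate seeds therefore share one gene universe and remain
scorable by a single trained signature, and adding a tissue to the
configuration does not perturb the draws of the others.

**What the generator does not emulate.** Realistic gene–gene correlation
beyond the single latent factor, library-size artifacts, compositional
effects of bulk mixtures, multimodal expression, or single-cell data.
Consequently, passing tests demonstrate that the *procedures* recover
known structure under a clean log-normal world — they do not certify
effect sizes on real tissue compendia, where cell-type composition and
batch structure add variance the simulator does not model.

# Verification scenarios and problem sizes

The test suite checks, among others:

* gradient–objective consistency against central finite differences and
  agreement of the fitted optimum with a generic BFGS optimizer of the
  same objective (cosine > 0.999);
* signature recovery: ranking genes by fitted weight separates planted
  signature genes with AUROC ≥ 0.9 on the default 2000-gene, 50-stem
  training draw;
* scoring against a brute-force rank-then-Pearson oracle, monotone-
  transform invariance, and exact unit span;
* sign/power recovery over 100 replicate cohorts of the default
  configuration: every non-null tissue detected at FDR < 0.05 with the
  correct sign in at least 95 replicates, and the null tissue's
  false-positive fraction within Monte-Carlo tolerance of the nominal
  0.05;
* BH, OLS, Kruskal–Wallis and Welch statistics against independent
  textbook-formula implementations;
* confounder adjustment on a deliberately *strongly* confounded scenario
  (one 300-sample tissue, sex effect 1.2 latent units, old-skewed female
  sampling): the scenario is designed so the marginal slope's bias is
  many times the estimator's standard error — under weak confounding the
  adjusted and unadjusted estimators are statistically
  indistinguishable and the comparison would measure noise, not
  adjustment. The adjusted age coefficient must land closer to the
  ground-truth effect (converted to the score scale via the
  latent-to-score regression slope) in at least 90 of 100 replicates;
* cross-tissue recovery: positive median off-diagonal correlation with
  the zero-loading tissue as the flattest row, and positive/negative
  pooled associations with the proliferation and senescence signals.

Replicated scenarios use 100 replicates of the default cohort
(10 × 300 samples × 2000 genes); module-level tests run on a reduced
3-tissue, 300-gene configuration. These sizes were chosen so the whole
suite runs comfortably on a laptop while leaving the Monte-Carlo bounds
meaningful.

# Known limitations

* The min–max rescaling makes scores cohort-relative; comparing absolute
  stemness across separately rescaled cohorts is not meaningful (raw
  scores are, up to signature coverage).
* The linear model assumes a linear age trend on the score scale; no
  spline or interaction terms in this version, and no subject-level
  random effects (a donor contributing many tissues violates independence
  across *tissues*, though each per-tissue fit is internally valid).
* `log2fc` depends on the model-predicted scores at reference covariate
  levels and is undefined when predictions cross zero — expected when a
  tissue's stemness sits near the cohort floor.
* p-values on cross-tissue matrix entries are deliberately not reported;
  overlap counts are, and the mask threshold (`minOverlap`) is the
  honest control for unstable pairs.
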