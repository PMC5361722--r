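---
title: "Absolute gene signature activation calling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute gene signature activation calling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigact)
```

# The problem

A gene signature is a set of genes whose coordinated over- or
under-expression marks the activation of a biological process. Popular
single-sample scoring tools are *relative*: a sample's score is only
interpretable against the score distribution of a comparison cohort, so a
patient's call changes when the cohort's composition changes (receptor
status, grade, subtype mix). `sigact` implements a two-stage method that ends
in an *absolute* classifier: the call for a profile is a pure function of the
profile and a frozen model.

# The region of independence

## Model

For a signature with $k$ genes measured over $n$ samples, each gene ranks
all samples by ascending expression, ties receiving average ranks. Genes in
the down-regulated subset are negated before ranking, so every gene orders
samples from least to most activated. The per-sample rank-sum
$R_s = \sum_{g=1}^{k} \mathrm{rank}_g(s)$ induces a linear order of the
cohort from "turned off" to "turned on".

The null model asks where a sample with *no* coherent signature signal would
land: an artificial sample $n+1$ is ranked by each gene with an independent
uniform draw from $\{0, 1, \dots, n+1\}$ and the $k$ draws are summed. This
is repeated `n_trials` times (default 10,000). The region of independence at
coverage $q$ (ROI$_q$, default $q = 0.95$) is the closed interval between
the $(1-q)/2$ and $(1+q)/2$ empirical quantiles of these null sums. Observed
rank-sums below the region are labelled **low**, above it **high**, inside
it (bounds included) **independent**.

## Numerical choices

* **Integer null draws.** The draw domain $\{0,\dots,n+1\}$ is the literal
  artificial-patient construction; a continuous-uniform variant on
  $(0, n+1)$ is available via `draw = "continuous"`. Both are isolated
  behind `null_rank_sums()`.
* **Nearest-rank (type 1) quantiles.** Both bounds are attainable null
  values, and the closed interval provably contains at least a fraction $q$
  of the trials; empirically the mean coverage sits at $\approx 0.9502$ for
  10,000 trials. `roi_null_pmf()` / `roi_region_exact()` provide the exactly
  enumerated null (the $(n+2)^k$-outcome distribution computed by
  convolution) against which the sampled bounds are validated.
* **Ties.** Tied expression receives average ranks, keeping the rank-sum
  scale aligned with the integer null; rank-sums exactly on a region bound
  are labelled independent — activation is never called without evidence.
* **Symmetric two-sided region.** The region is defined by symmetric tail
  quantiles, matching the interpretation of a central band of null
  positions.
* **Reproducibility.** One RNG stream is derived per (signature, seed), so
  batch results do not depend on processing order.
* `min_genes` (default 5): signatures with fewer genes present are skipped
  (reported, not errored, in batch runs) — a rank-sum over very few genes
  has too coarse a null to be informative.

The partition is deliberately cohort-level: adding samples changes $n$, the
null, and potentially other samples' labels. That instability is what the
second stage removes.

# Winnowing

Not every curated signature is informative in a given tissue. `winnow()`
computes, per signature, the fraction of samples labelled independent and
declares the signature informative iff that fraction is at most 0.8 (strict
"exceeds" reading of the cutoff, exposed as `cutoff`). As a negative
control the same statistic is computed after one global permutation of the
dataset's gene labels, which breaks gene–gene correlation and should push
every signature towards fully independent. The control is computed once per
dataset and shared by all signatures, since the permutation operates on the
dataset, not on a signature; a per-signature repeat is available by calling
`permute_gene_labels()` directly.

# The absolute model

## Gold standard

`build_gold_standard()` applies the ROI to every training dataset
*separately* — platform scales differ, so a pooled ranking across merged
cohorts would be meaningless — and attaches dataset-balanced weights
$w_i = 1/(D\,n_d)$ for a sample in dataset $d$ of size $n_d$ among $D$
datasets. Every dataset then carries total weight $1/D$ regardless of its
size, and replicating samples within a dataset leaves all weighted
quantities unchanged.

## Rule mining

For every ordered pair of genes $(x, y)$ in the shared universe and every
class $c$, the binary rule $r$: "$\mathrm{expr}(x) > \mathrm{expr}(y)$
within the sample" is scored by

$$ s(r, c) = \hat W(r\,\mathrm{true} \mid c) - \hat W(r\,\mathrm{true} \mid \bar c), $$

the weighted in-class minus out-of-class frequency. This is the simplest
statistic expressing "how strongly the rule is associated with the class";
it is exposed behind `score_pair_rules()` so alternatives (e.g. mutual
information) can be swapped in. Because rules only compare genes within one
sample, scores — and everything downstream — are invariant to per-sample
monotone distortions, which is what buys cross-platform robustness.

The candidate list interleaves the per-class rankings (high, low,
independent, repeating, duplicates removed) so that no class is starved of
rules by a single pooled ranking. Genes may appear in several rules; the
trainer deduplicates rules, not genes.

## Choosing K and fitting

The rule count $K$ is chosen from `k_grid` (default $1,\dots,50$ — the
model is meant to be compact; larger grids are supported but rarely help) by
10-fold cross-validation, stratified jointly by class and dataset, with
rules *re-ranked inside each training fold* so selection bias from the full
data does not leak into the estimate. The criterion is held-out weighted
kappa; ties go to the smallest $K$. If the rarest class has fewer members
than folds, the fold count is reduced with a warning.

The $K$ rules are combined by naive Bayes. With weighted counts rescaled to
an effective sample size of $n$ (so that equal weights give plain counts),

$$ P(r\,\mathrm{true} \mid c) = \frac{m_{rc} + \alpha}{n_c + 2\alpha},
   \qquad \alpha = 1, $$

with Laplace smoothing preventing zero probabilities, and priors equal to
the weighted class frequencies (a uniform-prior variant can be obtained by
rehydrating a model with modified priors via `sigact_model()`). Posteriors
are computed in log space to avoid underflow at large $K$.

## Filtering

A candidate model is retained only if its agreement with the gold standard
is significant in *every* individual training dataset:
$p_{\kappa} \cdot n_{\mathrm{tests}} < \alpha$ with $\alpha = 0.05$, where
the Bonferroni family $n_{\mathrm{tests}}$ is the number of candidate models
(the family size is recorded in the fit). Requiring significance in each
dataset separately is what makes the retained models portable across
platforms.

Two pipeline filters act in sequence: winnowing removes signatures whose
cohort partition is random-like *before* any model is fit, and the kappa
filter removes models that fail to mimic their (informative) gold standard.
Both are needed: on data where a gene set's extreme rank-sums reflect
genuine single-sample structure, a classifier can legitimately learn the
tails of even a biologically meaningless partition, so the kappa filter
alone cannot identify uninformative signatures — that is winnowing's job.

## Prediction

`predict()` on a model evaluates each rule on one profile (strict `>`; ties
evaluate false — a measure-zero event on continuous data), drops rules with
missing genes (refusing above a 50% missingness threshold, configurable),
renormalizes the likelihood over the evaluated rules, and returns the
posterior over the three classes; posterior ties fall back to independent.
Batch prediction is defined as the column-wise map of single-profile
prediction, so a sample's call is bit-identical alone, in any batch, and in
any column order.

# Agreement statistics

Cohen's kappa is $\kappa = (p_o - p_e)/(1 - p_e)$; significance uses the
classical large-sample null variance
$\mathrm{var}_0 = [p_e + p_e^2 - \sum_i r_i c_i (r_i + c_i)] / [n (1-p_e)^2]$
with a two-sided normal p-value. The formula is validated against a
label-permutation null in the test suite, which is the authoritative check;
at moderate $n$ the normal approximation is accurate to a few thousandths
near conventional significance levels. Fisher association uses the exact
network algorithm with a seeded Monte-Carlo fallback for large tables; FDR
control is standard Benjamini–Hochberg; a Kruskal–Wallis utility covers
score-versus-class association.

# The instability experiment

`stability_experiment()` scores every sample twice — in the full cohort and
in the sample's stratum only — and records $|s_{\mathrm{all}} -
s_{\mathrm{stratum}}|$. The bundled relative scorer is the z-score combiner
$\mathrm{score}(s) = \sum_g z_{gs}/\sqrt{k}$ (population-sd
standardization by default for determinism; sample sd via `sd_type`), with
down genes negated after standardization; it is the one relative method
fully specified by a single formula, and the harness accepts any scorer
function so external implementations can be plugged in. Because z-score
shifts are symmetric in sign (re-centring moves scores both ways), the
departure from zero is tested with a one-sample signed-rank test on the
absolute shifts. For the absolute scorer (`sigact_scorer()`, posterior
contrast $p_{\mathrm{high}} - p_{\mathrm{low}}$) the shift is exactly zero
by construction, not approximately.

# The synthetic-data generator

`simulate_cohort()` generates the structure the ROI assumes. Background
expression is exponentiated Gaussian (log-normal-like, log-mean 6, log-sd 1
by default), resembling raw non-negative intensities. For each planted
signature, a disjoint gene block of size $k$ is assigned; high-block samples
gain $+\delta\,\sigma$ on up genes and $-\delta\,\sigma$ on down genes on
the log scale, low-block samples the mirror image, and independent-block
samples receive a per-(gene, sample) shift of magnitude $\delta\,\sigma$
with independent random sign — each gene still varies strongly, but the
genes lose their pairwise correlation, which is precisely the independent
class's definition. Default design parameters ($n = 500$, $k = 50$,
fractions 0.3/0.4/0.3, $\delta = 3$, $\sigma = 1$) describe a strong,
clearly recoverable signal; $\delta$ is the single knob that moves the
design from unrecoverable ($\delta = 0$) to saturated.

`simulate_multidataset()` shares the gene universe and signature assignment
across cohorts, draws fresh samples per cohort (optionally with skewed class
fractions, mimicking composition imbalance between studies), and distorts
each cohort with a global power transform $\mathrm{expr} \mapsto
e^{b}\,\mathrm{expr}^{a}$. `simulate_platform_pair()` renders one cohort on
two synthetic platforms with distinct global power transforms plus per-cell
log-normal noise. The deterministic part of a platform distortion is
profile-wide monotone by design: gene-pair rules compare two genes within a
sample, so only transforms applied consistently across a profile leave
predictions exactly invariant, and gene-wise heterogeneity between platforms
is represented by the stochastic noise term instead. With zero noise the
two renderings therefore agree exactly; with noise, agreement degrades
smoothly but stays far above a label-shuffled background.

What the generator does *not* emulate: gene–gene correlation in the
background (real co-expression networks), heavy-tailed and
platform-specific error distributions, batch effects within a dataset, and
missingness. Passing tests demonstrate correctness of the algorithms under
the stated generative model, not clinical performance on real cohorts.

# Problem sizes and verification

The test suite validates every stage against independent oracles: exhaustive
enumeration for the null pmf and region bounds (small $n$, $k$),
hand-computed arithmetic for weights, rule scores and naive Bayes tables, a
brute-force double loop for pair scoring, permutation nulls for kappa, and
hypergeometric enumeration for Fisher. End-to-end checks use 200-run
coverage studies ($n = 200$, $k = 20$), 100-replicate null-cohort studies
($n = 500$, $k = 50$), a planted-recovery study at $\delta = 3$, and a
four-cohort experiment (three training cohorts of 200 samples, a 500-gene
universe, five planted plus five noise signatures, validation on the fourth
cohort) in which every planted model is retained and transfers with
significant held-out kappa while no noise signature survives the pipeline.
These sizes were chosen as the smallest designs at which the studied
quantities are stable.

# Known limitations

* The ROI needs a reasonably large cohort (warning below 200 samples) and is
  intentionally cohort-dependent; it is a labelling device, not a
  single-sample method.
* Rule mining is quadratic in the gene universe; training is meant to run on
  a curated universe (the shared-platform gene set), not a whole
  transcriptome.
* The kappa filter tests agreement in the training datasets; genuinely
  out-of-sample validation requires a held-out cohort, as in the end-to-end
  tests.
* Independent-class predictions are inherently less reliable than low/high:
  the class is defined by absence of signal.
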