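# sigact — absolute single-sample gene signature activation calling

`sigact` answers a practical question in transcriptomics: *given one gene
expression profile — one tumour, one patient, one cell population — is a given
biological process (a gene signature) activated, repressed, or neither?*

Most single-sample pathway tools (ssGSEA, GSVA, PLAGE, z-score, …) are
**relative**: the score for a sample must be interpreted against the
distribution of scores in a larger cohort, so the call for one patient changes
when the composition of the comparison cohort changes (e.g. the fraction of
ER-positive tumours). `sigact` implements an **absolute** alternative: a
classifier whose output for one sample depends only on that sample and a
frozen trained model.

## The method

Two components, trained in sequence:

**1. The region of independence (ROI_q)** — a cohort-level rank-sum
permutation procedure. For a signature of *k* genes over *n* samples, each
gene ranks all samples by ascending expression (down-regulated genes are
negated first, so every gene orders samples in the direction of activation);
each sample's *k* ranks are summed and the cohort is linearly ordered by the
sum. The null: an artificial sample *n + 1* is ranked by every gene with an
independent uniform draw from {0, …, *n* + 1} and its rank-sum recorded, for
10,000 trials. The ROI at coverage *q* (default 0.95) is the closed interval
between the (1−q)/2 and (1+q)/2 nearest-rank quantiles of the null rank-sums.
Samples below it are called **low**, above it **high**, inside it
**independent** (no coherent signature signal). A winnowing step discards
signatures whose independent fraction exceeds 0.8 — partitions
indistinguishable from random gene sets.

**2. The absolute model** — per signature, a classifier mimicking the ROI
labels ("gold standard", computed per dataset, never on a merged matrix) from
a single profile. Every ordered gene pair (x, y) defines a binary rule
"expr(x) > expr(y) within the sample" — invariant to monotone transforms and
hence platform-robust. Rules are scored by dataset-balanced weighted
in-class vs out-of-class frequency difference, the top *K* rules (chosen by
10-fold cross-validation) are combined by naive Bayes, and only models whose
agreement with the gold standard is significant (Bonferroni-corrected
Cohen's kappa p < 0.05) in **every** training dataset are retained.

The package also ships the agreement statistics used throughout (Cohen's
kappa with large-sample significance, Fisher association, BH FDR), a
cohort-composition instability experiment contrasting relative z-score
scoring with the absolute model, and a synthetic-cohort generator with
planted low/independent/high structure that makes the whole pipeline testable
without any external data.

## Worked example

```r
library(sigact)

# three synthetic cohorts sharing one planted signature (k = 20, effect 3 sd,
# 30% low / 40% independent / 30% high), plus per-dataset platform distortion
sims  <- simulate_multidataset(n_datasets = 3, n_samples = 150, n_genes = 200,
                               sig_specs = data.frame(k = 20, frac_low = 0.3,
                                                      frac_high = 0.3, delta = 3,
                                                      frac_down = 0.2),
                               seed = 42)
exprs <- lapply(sims$datasets, `[[`, "expr")

# cohort-level partition for one dataset
r <- roi(exprs[[1]], sims$signatures[[1]], seed = 42)
print(r)
#> Region-of-independence partition for signature 'sim_sig_01'
#>   samples: 150, signature genes used: 20
#>   region (q = 0.95): [1128.0, 1893.0] from 10000 null trials
#>         low independent        high
#>          45          57          48

# train the absolute single-sample model on all three cohorts
fit <- sigact(exprs, sims$signatures, n_trials = 5000, k_grid = 1:25, seed = 42)
summary(fit)
#>   signature_id K min_kappa max_p_bonferroni retained
#> 1   sim_sig_01 5 0.7430999      1.22741e-40     TRUE

# call activation from ONE profile — no cohort needed
predict(fit$models[["sim_sig_01"]], exprs[[1]][, 1])
#>   sample_id signature_id label     p_low p_independent       p_high
#> 1    sample   sim_sig_01   low 0.9052492     0.0947508 4.618295e-09
```

Reading the output: the ROI partitions the 150-sample cohort into 45 low / 57
independent / 48 high, recovering the planted 30/40/30 design; its region
`[1128, 1893]` brackets 95% of the null rank-sums. The trained model needs
only 5 gene-pair rules, agrees with the cohort-level gold standard at kappa ≥
0.74 in every training dataset (hence `retained`), and calls the first sample
`low` with posterior 0.905 from its profile alone. The same call is returned
whatever other samples are loaded alongside — the absoluteness the package
exists for.

Models serialize to versioned JSON (`write_models()` / `read_models()`) for
reuse on new samples.

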